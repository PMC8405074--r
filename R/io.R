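# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV (genes x samples), GMT gene-set libraries, two-column
# edge lists, survival tables and qPCR Ct tables. All readers validate
# strictly and fail with the offending line/field named; all writers
# round-trip through the matching reader.

#' Construct an expression matrix container
#'
#' @param values Numeric gene-by-sample matrix (log2 scale) with unique
#'   rownames (gene symbols) and colnames (sample identifiers).
#' @param groups Character vector of group labels, one per sample, named by
#'   sample identifier (order-free) or unnamed in column order.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (named character, aligned to columns).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    nm_stop("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    nm_stop("expression matrix needs gene rownames and sample colnames")
  }
  rownames(values) <- normalize_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    nm_stop("duplicate gene symbols after normalization: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) nm_stop("duplicate sample identifiers")
  if (any(!is.finite(values))) nm_stop("expression matrix contains non-finite values")
  groups <- as.character(groups) |> stats::setNames(names(groups))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values)) nm_stop("one group label per sample required")
    names(groups) <- colnames(values)
  }
  unknown <- setdiff(names(groups), colnames(values))
  if (length(unknown)) nm_stop("unknown sample in group assignment: ", paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) nm_stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  structure(list(values = values, groups = groups[colnames(values)]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples; groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' symbols. Symbols are upper-cased; duplicate symbol rows are collapsed to
#' the row with the highest mean expression (the usual probe-to-gene
#' convention for microarray matrices). Missing or non-numeric cells are
#' rejected with the row and column named.
#'
#' @param path Path to the TSV file.
#' @param group_assignment Named character vector (sample -> group label) or
#'   path to a two-column TSV `sample<TAB>group` with header.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, group_assignment) {
  lines <- readLines(path)
  if (length(lines) < 2) nm_stop("parse error: ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) nm_stop("parse error line 1: expected gene column plus samples")
  samples <- header[-1]
  n_field <- length(header)
  genes <- character(length(fields) - 1)
  vals <- matrix(NA_real_, nrow = length(fields) - 1, ncol = length(samples))
  for (i in seq_along(fields)[-1]) {
    f <- fields[[i]]
    if (length(f) != n_field) {
      nm_stop("parse error line ", i, ": expected ", n_field, " fields, got ", length(f))
    }
    genes[i - 1] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      nm_stop("parse error line ", i, " (gene ", f[1], "), column '",
              samples[j], "': non-numeric value '", f[-1][j], "'")
    }
    vals[i - 1, ] <- v
  }
  genes <- normalize_symbols(genes)
  # collapse duplicate symbols: keep the row with highest mean expression
  if (anyDuplicated(genes)) {
    keep <- tapply(seq_along(genes), genes, function(idx) {
      idx[which.max(rowMeans(vals[idx, , drop = FALSE]))]
    })
    keep <- sort(unname(keep))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (is.character(group_assignment) && length(group_assignment) == 1 &&
      is.null(names(group_assignment)) && file.exists(group_assignment)) {
    g <- utils::read.delim(group_assignment, header = TRUE, sep = "\t",
                           colClasses = "character")
    if (!all(c("sample", "group") %in% names(g))) {
      nm_stop("parse error: group file needs 'sample' and 'group' columns")
    }
    group_assignment <- stats::setNames(g$group, g$sample)
  }
  expression_matrix(vals, group_assignment)
}

#' Write an expression matrix as TSV (round-trips through [read_expression()])
#' @param x An `expr_matrix`.
#' @param path Output TSV path.
#' @param groups_path Optional path for a sample/group sidecar TSV.
#' @export
write_expression <- function(x, path, groups_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(data.frame(sample = names(x$groups), group = unname(x$groups)),
                       groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT dialect: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' Member symbols are upper-cased and de-duplicated within each set.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_library`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) nm_stop("parse error: ", path, " is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  desc <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) nm_stop("parse error line ", i, ": GMT line needs >= 3 fields")
    nms[i] <- f[1]
    desc[i] <- f[2]
    genes <- unique(normalize_symbols(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) nm_stop("parse error line ", i, ": empty gene set '", f[1], "'")
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    nm_stop("parse error: duplicate term name(s): ",
            paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(sets, descriptions = stats::setNames(desc, nms), class = "gene_set_library")
}

#' Write a gene-set library to GMT
#' @param library A `gene_set_library` or named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  desc <- attr(library, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(library)), names(library))
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, desc[[nm]], library[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an interaction network container
#'
#' Simple undirected graph over gene symbols: self-loops are rejected,
#' duplicate and reversed pairs are merged.
#'
#' @param edges Two-column character matrix or data.frame of symbol pairs.
#' @param nodes Optional character vector of node symbols (to carry isolated
#'   nodes); defaults to the symbols appearing in `edges`.
#' @return An `interaction_network`: list with `nodes` and a two-column
#'   `edges` matrix in canonical (sorted-pair) order.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2) nm_stop("edges need two columns")
  if (length(edges)) {
    edges <- cbind(normalize_symbols(edges[, 1]), normalize_symbols(edges[, 2]))
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) nm_stop("self-loop(s) not allowed: ", paste(unique(edges[loops, 1]), collapse = ", "))
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    edges <- cbind(from = a[keep], to = b[keep])
  } else {
    edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  nodes <- if (is.null(nodes)) sort(unique(c(edges))) else sort(unique(normalize_symbols(nodes)))
  unknown <- setdiff(unique(c(edges)), nodes)
  if (length(unknown)) nm_stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a two-column edge-list TSV into an interaction network
#'
#' A third (weight) column, if present, is ignored. Self-loops are dropped
#' with a warning; duplicate and reversed pairs are merged. No header row.
#'
#' @param path Path to the edge-list TSV.
#' @return An [interaction_network()].
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) nm_stop("parse error: ", path, " is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) nm_stop("parse error line ", bad[1], ": need two symbol columns")
  a <- normalize_symbols(vapply(fields, `[`, "", 1))
  b <- normalize_symbols(vapply(fields, `[`, "", 2))
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped: ",
            paste(unique(a[loops]), collapse = ", "), call. = FALSE)
  }
  interaction_network(cbind(a[!loops], b[!loops]), nodes = unique(c(a, b)))
}

#' Write an interaction network as a two-column edge-list TSV
#' @param net An `interaction_network`.
#' @param path Output path.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_typed_table <- function(path, spec) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    nm_stop("parse error: missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(spec)) {
    if (spec[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(v)) {
        nm_stop("parse error: non-numeric value in column '", col, "' at data row ",
                which(is.na(v))[1])
      }
      df[[col]] <- v
    }
  }
  df
}

#' Read a survival table (subject, time, event, expression)
#'
#' `time` must be positive follow-up (years); `event` is 1 for an observed
#' event, 0 for censoring; `expression` is the stratifying gene's value.
#'
#' @param path TSV path with header `subject  time  event  expression`.
#' @return A data.frame with typed columns.
#' @export
read_survival <- function(path) {
  df <- read_typed_table(path, c(subject = "character", time = "numeric",
                                 event = "numeric", expression = "numeric"))
  if (any(df$time <= 0)) nm_stop("parse error: 'time' must be > 0 (row ", which(df$time <= 0)[1], ")")
  if (!all(df$event %in% c(0, 1))) {
    nm_stop("parse error: 'event' must be 0 or 1 (row ", which(!df$event %in% c(0, 1))[1], ")")
  }
  df[c("subject", "time", "event", "expression")]
}

#' Read a qPCR Ct table (sample, group, ct_target, ct_housekeeping)
#'
#' Ct values must be finite and positive; at least two groups must be
#' present for comparative analysis.
#'
#' @param path TSV path with header `sample  group  ct_target  ct_housekeeping`.
#' @return A data.frame with typed columns.
#' @export
read_qpcr <- function(path) {
  df <- read_typed_table(path, c(sample = "character", group = "character",
                                 ct_target = "numeric", ct_housekeeping = "numeric"))
  ct <- c(df$ct_target, df$ct_housekeeping)
  if (any(!is.finite(ct) | ct <= 0)) nm_stop("parse error: Ct values must be finite and positive")
  if (length(unique(df$group)) < 2) nm_stop("parse error: at least 2 groups required")
  df[c("sample", "group", "ct_target", "ct_housekeeping")]
}

#' Write any data.frame as a TSV (round-trippable)
#' @param rows A data.frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the planted-truth sidecar (key=value text)
#'
#' @param truth Named list; vector values are comma-joined.
#' @param path Sidecar path.
#' @export
write_truth <- function(truth, path) {
  lines <- vapply(names(truth), function(k) {
    paste0(k, "=", paste(truth[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  stats::setNames(out, vapply(kv, `[`, "", 1))
}
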