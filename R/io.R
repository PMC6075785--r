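# Readers and writers for the plain-text formats of the pipeline. All files
# are TSV with '#' comment lines; writers stamp a manifest reference so every
# output can be traced to the run that produced it.

.read_lines_nocomment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an interaction edge list
#'
#' @param path TSV file with at least two columns; lines starting with `#`
#'   are skipped. An optional numeric third column is taken as edge weight.
#' @param kind `"network"` or `"ppi"` for undirected edges (pairs
#'   canonicalized and deduplicated, reversed duplicates collapse),
#'   `"tf"` for directed regulator-to-target edges (exact duplicates
#'   collapse).
#' @return data.frame with columns `a`, `b` (and `weight` when present);
#'   attribute `n_self_loops` counts retained self-loops.
#' @export
read_edge_list <- function(path, kind = c("network", "ppi", "tf")) {
  kind <- match.arg(kind)
  src <- .read_lines_nocomment(path)
  if (!length(src$lines)) stop("empty edge list: ", path)
  parts <- strsplit(src$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2L ||
                        !nzchar(p[1]) || !nzchar(p[2]), logical(1)))
  if (length(bad))
    stop("malformed row in ", path, " at line ", src$lineno[bad[1]])
  a <- vapply(parts, `[`, "", 1); b <- vapply(parts, `[`, "", 2)
  w <- vapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(p[3])) suppressWarnings(as.numeric(p[3]))
    else 1
  }, numeric(1))
  if (anyNA(w)) {
    i <- which(is.na(w))[1]
    stop("non-numeric weight in ", path, " at line ", src$lineno[i])
  }
  if (kind %in% c("network", "ppi")) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste0(lo, "\r", hi))
    out <- data.frame(a = lo[keep], b = hi[keep], weight = w[keep])
  } else {
    keep <- !duplicated(paste0(a, "\r", b))
    out <- data.frame(a = a[keep], b = b[keep], weight = w[keep])
  }
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- sum(out$a == out$b)
  out
}

#' Write an edge list
#' @param edges data.frame with two id columns (optional weight).
#' @param path output path.
#' @param manifest optional manifest path stamped as a comment header.
#' @export
write_edge_list <- function(edges, path, manifest = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste0("# manifest: ", manifest), con)
  has_w <- "weight" %in% names(edges)
  writeLines(paste(edges[[1]], edges[[2]],
                   if (has_w) edges$weight else NULL, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT pathway collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicate set names and member-less lines are fatal.
#'
#' @param path GMT file.
#' @return a [pathway_collection()] with `source` set to the file name.
#' @export
read_gmt <- function(path) {
  src <- .read_lines_nocomment(path)
  if (!length(src$lines)) stop("empty GMT file: ", path)
  parts <- strsplit(src$lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1]
    stop("duplicate pathway name '", d, "' in ", path, " (lines ",
         paste(src$lineno[nm == d], collapse = ", "), ")")
  }
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line without members in ", path, " at line ",
         src$lineno[short[1]])
  sets <- lapply(parts, function(p) p[-(1:2)])
  desc <- vapply(parts, `[`, "", 2)
  pathway_collection(stats::setNames(sets, nm), descriptions = desc,
                     source = basename(path))
}

#' Write a GMT pathway collection
#' @param collection a [pathway_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with sample labels
#'
#' @param matrix_path TSV: header row of sample names (first column header
#'   arbitrary), then one row per gene. Non-numeric cells and duplicate gene
#'   rows are fatal.
#' @param labels_path TSV with two columns (sample, group); every sample
#'   column must be labeled.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  df <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression matrix needs >= 1 sample column")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene row '", genes[duplicated(genes)][1], "' in ",
         matrix_path)
  mat <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", matrix_path, " at gene '",
         genes[idx[1]], "', sample '", colnames(mat)[idx[2]], "'")
  }
  rownames(num) <- genes; colnames(num) <- colnames(mat)
  lab <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                           comment.char = "#", colClasses = "character")
  if (ncol(lab) < 2L) stop("label file needs two columns (sample, group)")
  lab <- lab[lab[[1]] != "sample", , drop = FALSE]  # tolerate a header row
  labels <- stats::setNames(lab[[2]], lab[[1]])
  unlab <- setdiff(colnames(num), names(labels))
  if (length(unlab))
    stop("unlabeled sample(s): ", paste(unlab, collapse = ", "))
  expression_dataset(num, labels[colnames(num)])
}

#' Write an expression dataset
#' @param data an [expression_dataset()].
#' @param matrix_path,labels_path output paths.
#' @export
write_expression <- function(data, matrix_path, labels_path) {
  stopifnot(inherits(data, "expression_dataset"))
  df <- data.frame(gene = rownames(data$values), data$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(data$values),
               group = as.character(data$groups)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(matrix_path)
}

#' Read a two-column table (e.g. domain annotations, drug targets)
#' @param path TSV with >= 2 columns; `#` comments skipped.
#' @param what label used in error messages.
#' @return data.frame with the first two columns.
#' @export
read_two_column <- function(path, what = "table") {
  src <- .read_lines_nocomment(path)
  if (!length(src$lines)) stop("empty ", what, " file: ", path)
  parts <- strsplit(src$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2L ||
                        !nzchar(p[1]) || !nzchar(p[2]), logical(1)))
  if (length(bad))
    stop("malformed row in ", path, " at line ", src$lineno[bad[1]])
  data.frame(a = vapply(parts, `[`, "", 1),
             b = vapply(parts, `[`, "", 2))
}

#' Read a one-gene-per-line list
#' @param path text file, `#` comments skipped.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  src <- .read_lines_nocomment(path)
  trimws(src$lines)
}

#' Read a fusion description file
#'
#' Simple key-value format, one `key = value` per line: `parent5`,
#' `parent3`, `retained5`, `retained3` (comma-separated accession lists;
#' retained lists may be empty).
#'
#' @param path config file.
#' @param annotations a [domain_annotation()] table.
#' @return a [fusion_spec()].
#' @export
read_fusion_spec <- function(path, annotations) {
  src <- .read_lines_nocomment(path)
  kv <- strsplit(src$lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) < 2L)
  if (length(bad))
    stop("malformed line in ", path, " at line ", src$lineno[bad[1]])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  get <- function(k, required = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (required) stop("missing key '", k, "' in ", path)
      return("")
    }
    vals[i]
  }
  split_list <- function(s) {
    if (!nzchar(s)) character() else trimws(strsplit(s, ",")[[1]])
  }
  fusion_spec(get("parent5"), get("parent3"),
              retained5 = split_list(get("retained5", required = FALSE)),
              retained3 = split_list(get("retained3", required = FALSE)),
              annotations = annotations)
}

#' Build a run manifest
#'
#' Records input-file MD5 digests, the configuration snapshot, tool version
#' and a timestamp; the manifest file name is stamped into every output the
#' run writes.
#'
#' @param inputs named character vector of input file paths.
#' @param config named list of configuration values.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(), config = list()) {
  digests <- if (length(inputs))
    vapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  else character()
  structure(
    list(tool = "fusenet",
         version = as.character(utils::packageVersion("fusenet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         inputs = as.list(digests), config = config),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# write a data.frame as TSV with a manifest comment header
.write_tsv <- function(df, path, manifest = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste0("# manifest: ", manifest), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
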