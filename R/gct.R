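# GCT v1.2 and CLS readers/writers (GenePattern-ecosystem formats).

#' Read an expression matrix from a GCT v1.2 file
#'
#' The expected layout is `#1.2`, then `<nrows>\t<ncols>`, then a header line
#' `Name  Description  <sample ids...>`, then one row per gene. Values are
#' parsed as doubles; gene descriptions are kept in the `"description"`
#' attribute of the returned matrix.
#'
#' @param path path to a GCT file.
#' @return a genes x samples numeric matrix with gene rownames, sample
#'   colnames and a `"description"` character attribute.
#' @export
read_gct <- function(path) {
  abort_if(!file.exists(path), sprintf("GCT file not found: %s", path))
  lines <- readLines(path)
  abort_if(length(lines) < 3, sprintf("%s: truncated GCT (fewer than 3 lines)", path))
  abort_if(trimws(lines[1]) != "#1.2",
           sprintf("%s:1: expected version line '#1.2', found '%s'", path, lines[1]))
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  abort_if(length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))),
           sprintf("%s:2: expected '<nrows>\\t<ncols>'", path))
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  abort_if(length(header) != nc + 2,
           sprintf("%s:3: header has %d sample columns, expected %d",
                   path, length(header) - 2, nc))
  sample_ids <- header[-(1:2)]
  abort_if(anyDuplicated(sample_ids) > 0,
           sprintf("%s:3: duplicate sample ids", path))

  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  abort_if(length(body) != nr,
           sprintf("%s: declared %d rows but found %d data lines",
                   path, nr, length(body)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  gene_ids <- character(nr)
  descriptions <- character(nr)
  values <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    f <- fields[[i]]
    abort_if(length(f) != nc + 2,
             sprintf("%s:%d: row has %d value columns, expected %d",
                     path, i + 3, length(f) - 2, nc))
    gene_ids[i] <- f[1]
    descriptions[i] <- f[2]
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    abort_if(anyNA(v), sprintf("%s:%d: non-numeric expression value", path, i + 3))
    values[i, ] <- v
  }
  dup <- gene_ids[duplicated(gene_ids)]
  abort_if(length(dup) > 0,
           sprintf("%s: duplicate gene ids (%s)", path,
                   paste(head(unique(dup), 3), collapse = ", ")))
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "description") <- descriptions
  values
}

#' Write an expression matrix as GCT v1.2
#'
#' Values are printed with 15 significant digits, so a write/read round trip
#' is lossless well beyond the 6 significant digits the format is documented
#' to guarantee.
#'
#' @param matrix genes x samples numeric matrix with dimnames.
#' @param path output file path.
#' @param description optional per-gene description column (defaults to the
#'   matrix's `"description"` attribute, else the gene ids).
#' @export
write_gct <- function(matrix, path, description = NULL) {
  check_expression_matrix(matrix)
  description <- description %||% attr(matrix, "description") %||%
    rownames(matrix)
  abort_if(length(description) != nrow(matrix),
           "`description` must have one entry per gene")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(matrix)),
                   collapse = "\t"), con)
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], description[i],
            format(matrix[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read class labels from a CLS file
#'
#' Space-delimited categorical CLS: `<n> <k> 1`, then `# <label names>`, then
#' one entry per sample (either label names or 0-based indices into the
#' label-name line).
#'
#' @param path path to a CLS file.
#' @return a character vector of per-sample labels.
#' @export
read_cls <- function(path) {
  abort_if(!file.exists(path), sprintf("CLS file not found: %s", path))
  lines <- readLines(path)
  abort_if(length(lines) < 3, sprintf("%s: truncated CLS", path))
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  abort_if(length(hdr) < 2, sprintf("%s:1: expected '<n> <k> 1'", path))
  n <- hdr[1]; k <- hdr[2]
  abort_if(!startsWith(trimws(lines[2]), "#"),
           sprintf("%s:2: expected '# <label names>'", path))
  names_ <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  abort_if(length(names_) != k,
           sprintf("%s:2: %d label names declared but %d listed",
                   path, k, length(names_)))
  entries <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  abort_if(length(entries) != n,
           sprintf("%s:3: %d samples declared but %d labels listed",
                   path, n, length(entries)))
  idx <- suppressWarnings(as.integer(entries))
  if (!anyNA(idx) && all(idx >= 0 & idx < k)) {
    labels <- names_[idx + 1]
  } else {
    abort_if(!all(entries %in% names_),
             sprintf("%s:3: labels not among the declared names", path))
    labels <- entries
  }
  labels
}

#' Write class labels as a CLS file
#'
#' @param labels character vector of per-sample labels (or a tibble with a
#'   `label` column).
#' @param path output file path.
#' @export
write_cls <- function(labels, path) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  abort_if(length(labels) == 0, "no labels to write")
  lv <- unique(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(labels), length(lv), 1), con)
  writeLines(paste("#", paste(lv, collapse = " ")), con)
  writeLines(paste(labels, collapse = " "), con)
  invisible(path)
}
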