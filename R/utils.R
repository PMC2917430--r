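# Internal helpers shared across modules.

# Evaluate `code` under a fixed, named RNG so that identical seeds give
# identical draws across platforms and R versions.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# An expression matrix is a finite numeric matrix with unique gene row names
# and unique sample column names.
check_expression_matrix <- function(x, arg = "matrix") {
  abort_if(!is.matrix(x) || !is.numeric(x),
           sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  abort_if(is.null(rownames(x)) || is.null(colnames(x)),
           sprintf("`%s` must carry gene rownames and sample colnames", arg))
  abort_if(anyDuplicated(rownames(x)) > 0,
           sprintf("duplicate gene ids in `%s`", arg))
  abort_if(anyDuplicated(colnames(x)) > 0,
           sprintf("duplicate sample ids in `%s`", arg))
  abort_if(!all(is.finite(x)),
           sprintf("`%s` contains non-finite values", arg))
  invisible(TRUE)
}

# Class labels are accepted either as a two-column data frame
# (sample_id, label) or as a vector named by / aligned with the samples.
normalize_class_labels <- function(classes, sample_ids) {
  if (is.data.frame(classes)) {
    abort_if(!all(c("sample_id", "label") %in% names(classes)),
             "class-label data frame needs columns `sample_id` and `label`")
    idx <- match(sample_ids, classes$sample_id)
    abort_if(anyNA(idx), "class labels missing for some matrix samples")
    labels <- as.character(classes$label[idx])
  } else {
    labels <- as.character(classes)
    if (!is.null(names(classes)) && all(sample_ids %in% names(classes))) {
      labels <- labels[match(sample_ids, names(classes))]
    }
    abort_if(length(labels) != length(sample_ids),
             "class labels must match the number of samples")
  }
  labels
}
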