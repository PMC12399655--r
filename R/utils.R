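#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Coerce an expression input to a numeric matrix (genes x samples).
# Accepts a matrix with rownames, or a data frame whose first column
# (or a column named "gene") holds gene identifiers.
as_expr_matrix <- function(x, arg = "expr") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort(sprintf("`%s` must have gene identifiers as rownames.", arg))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    gene_col <- if ("gene" %in% names(x)) "gene" else names(x)[1]
    genes <- as.character(x[[gene_col]])
    m <- as.matrix(x[setdiff(names(x), gene_col)])
    rownames(m) <- genes
    storage.mode(m) <- "double"
    return(m)
  }
  abort(sprintf("`%s` must be a matrix or data frame of expression values.", arg))
}

# Row-wise sample SDs of a matrix without looping over genes.
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

# Row-wise means restricted to a column subset, kept as a named vector.
row_means_of <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  if (ncol(sub) == 1) drop(sub) else rowMeans(sub)
}

check_count <- function(x, min, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}

# Evaluate a Kaplan-Meier style step function stored as (times, surv) at t.
# strict = TRUE gives the left-hand limit S(t-).
step_surv_at <- function(times, surv, t, strict = FALSE) {
  idx <- if (strict) sum(times < t) else sum(times <= t)
  if (idx == 0) 1 else surv[idx]
}
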