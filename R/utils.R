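# Internal argument checks and small shared helpers.

N_STAGES <- 5L

STAGE_LABELS <- c("spat", "recruit", "juvenile", "medium", "large")

CLASS_COLS <- paste0("class_", 1:5)

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", arg))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", arg,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_count_vector <- function(n, arg = "n") {
  if (is.data.frame(n)) n <- counts_from_df(n)
  n <- as.numeric(n)
  if (length(n) != N_STAGES || anyNA(n)) {
    abort(sprintf("`%s` must be a numeric vector of %d non-missing counts.",
                  arg, N_STAGES))
  }
  if (any(n < 0)) {
    abort(sprintf("`%s` contains negative counts.", arg))
  }
  n
}

# Extract the 5 class-count columns of a single-row size-distribution tibble.
counts_from_df <- function(df) {
  missing_cols <- setdiff(CLASS_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("size distribution is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) != 1L) {
    abort("expected a single-row size distribution; filter to one row first.")
  }
  as.numeric(unlist(df[1, CLASS_COLS]))
}

# Coerce a transition_matrix or plain matrix to a 5x5 numeric matrix.
as_projection_matrix <- function(A, arg = "A") {
  if (inherits(A, "transition_matrix")) A <- A$A
  if (!is.matrix(A) || !is.numeric(A)) {
    abort(sprintf("`%s` must be a transition_matrix or a numeric matrix.", arg))
  }
  if (nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be square.", arg))
  }
  if (any(A < 0)) {
    abort(sprintf("`%s` must be nonnegative.", arg))
  }
  A
}

# Smallest value among those attaining the maximum frequency.
modal_value <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
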