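#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' computed from midrank sums for the first sample. The p-value is exact by
#' complete enumeration of all rank assignments when the pooled sample is
#' small (`n1 + n2 <= 16`) and tie-free; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used. The test is
#' invariant under strictly monotone transforms of the pooled data because it
#' depends on the observations only through their ranks.
#'
#' @param a,b numeric samples (nonempty, finite).
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`,
#'   stated for the first sample.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` selects automatically. Exact enumeration with ties is not
#'   supported and falls back to the approximation with a warning.
#' @return a `u_test` list: `u_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`, `alternative`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
mann_whitney_u <- function(a, b,
                           alternative = c("two_sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) {
    rlang::abort("both samples must be nonempty.")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    rlang::abort("samples must be finite.")
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- exact %||% (n1 + n2 <= 16L && !ties)
  if (use_exact && ties) {
    rlang::warn("exact enumeration is not defined with ties; using the normal approximation.")
    use_exact <- FALSE
  }

  if (use_exact) {
    p <- mwu_exact_p(u, n1, n2, alternative)
    method <- "exact"
  } else {
    p <- mwu_normal_p(u, r, n1, n2, alternative)
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_value = min(max(p, 0), 1),
                 method = method, n1 = n1, n2 = n2,
                 alternative = alternative),
            class = "u_test")
}

# exact null distribution of U by enumerating all C(n1+n2, n1) rank subsets
mwu_exact_p <- function(u, n1, n2, alternative) {
  n <- n1 + n2
  subsets <- utils::combn(n, n1)
  us <- colSums(subsets) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  switch(alternative,
    two_sided = {
      mu <- n1 * n2 / 2
      mean(abs(us - mu) >= abs(u - mu) - eps)
    },
    less = mean(us <= u + eps),
    greater = mean(us >= u - eps)
  )
}

# normal approximation with tie-corrected variance and continuity correction
mwu_normal_p <- function(u, r, n1, n2, alternative) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  switch(alternative,
    two_sided = 2 * stats::pnorm(-(max(abs(u - mu) - 0.5, 0)) / sigma),
    less = stats::pnorm((u - mu + 0.5) / sigma),
    greater = stats::pnorm(-(u - mu - 0.5) / sigma)
  )
}

#' @export
print.u_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$alternative, x$u_statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' @method tidy u_test
#' @export
tidy.u_test <- function(x, ...) {
  tibble::tibble(u_statistic = x$u_statistic, p_value = x$p_value,
                 method = x$method, alternative = x$alternative,
                 n1 = x$n1, n2 = x$n2)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: both inputs must be equal
#' length (>= 2), finite and non-constant.
#'
#' @param a,b numeric vectors.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    rlang::abort("`a` and `b` must have equal length >= 2.")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    rlang::abort("inputs must be finite.")
  }
  if (stats::sd(a) < .Machine$double.eps || stats::sd(b) < .Machine$double.eps) {
    rlang::abort("correlation undefined for constant input.")
  }
  min(max(stats::cor(a, b), -1), 1)
}

#' Metadata correlation matrix
#'
#' Pearson correlation matrix of the clinical metadata triplet TRS score,
#' age and tremor level (the level entering as the equally spaced numeric
#' code 0/1/2). A strong TRS-level correlation supports using level strata as
#' severity classes; a sizable age-level correlation flags age as a
#' confounder.
#'
#' @param dataset a [spiral_dataset()] (or any data frame with numeric
#'   `trs_score`, `age`, `tremor_level` columns), >= 3 complete subjects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a symmetric 3x3 correlation matrix with unit diagonal.
#' @export
metadata_correlations <- function(dataset,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vars <- c("trs_score", "age", "tremor_level")
  missing_cols <- setdiff(vars, names(dataset))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("dataset is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  m <- cbind(trs_score = as.numeric(dataset$trs_score),
             age = as.numeric(dataset$age),
             tremor_level = as.numeric(dataset$tremor_level))
  incomplete <- !stats::complete.cases(m)
  if (any(incomplete)) {
    who <- if (!is.null(dataset$subject_id)) {
      dataset$subject_id[incomplete]
    } else {
      which(incomplete)
    }
    rlang::abort(paste0("incomplete metadata for subjects: ",
                        paste(who, collapse = ", ")))
  }
  if (nrow(m) < 3L) {
    rlang::abort("at least 3 subjects with complete metadata are required.")
  }
  cm <- stats::cor(m, method = method)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}
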