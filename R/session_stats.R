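# Two-level nonparametric statistical design over a collection of sessions.
# Level 1 (within session): Spearman correlation between node sizes (local
# stability of each state) and node-average variables, one coefficient per
# session. Level 2 (group): one-sample Wilcoxon signed-rank test of the
# per-session coefficients against median zero. Between sessions:
# Spearman correlations of session-average node size / loop length against
# session-average variables.

.tm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an n! x n integer matrix (cached; n <= 9).
perm_matrix <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.tm_cache[[key]])) return(.tm_cache[[key]])
  pm <- matrix(1L, nrow = 1L, ncol = 1L)
  if (n > 1L) {
    for (m in 2:n) {
      prev <- pm
      blocks <- vector("list", m)
      for (pos in seq_len(m)) {
        blk <- matrix(0L, nrow = nrow(prev), ncol = m)
        blk[, pos] <- m
        blk[, -pos] <- prev
        blocks[[pos]] <- blk
      }
      pm <- do.call(rbind, blocks)
    }
  }
  .tm_cache[[key]] <- pm
  pm
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of average-rank vectors (ties
#' receive average ranks). The two-sided p-value comes from full permutation
#' enumeration for `n <= 9` (or when `exact = TRUE`) and from the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Constant
#' input (zero rank variance) yields a flagged undefined result rather than
#' propagating `NaN`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) permutation enumeration;
#'   `NULL` (default) enumerates for `n <= 9`.
#' @param p_value set `FALSE` to skip the p-value (returns `NA`), useful when
#'   only the coefficient feeds a downstream group test.
#' @return list with `rho`, `p`, `n`, `defined` (FALSE when either input has
#'   zero rank variance) and `method` ("permutation" or "t-approximation").
#' @export
spearman_cor <- function(x, y, exact = NULL, p_value = TRUE) {
  n <- length(x)
  if (length(y) != n) stop_data("x and y must have equal length")
  if (n < 3L) stop_data("need n >= 3, got ", n)
  if (anyNA(x) || anyNA(y)) stop_data("missing values in correlation input")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE,
                method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (!p_value) {
    return(list(rho = rho, p = NA_real_, n = n, defined = TRUE, method = "none"))
  }
  use_exact <- if (is.null(exact)) n <= 9L else isTRUE(exact)
  if (use_exact) {
    if (n > 10L) stop_config("exact permutation enumeration limited to n <= 10")
    pm <- perm_matrix(n)
    ry_perm <- matrix(ry[pm], nrow = nrow(pm))
    rho_perm <- as.vector(stats::cor(rx, t(ry_perm)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, defined = TRUE, method = method)
}

#' One-sample Wilcoxon signed-rank test against median zero
#'
#' Tests whether the median of `x` is `mu` (default 0). Exact zeros are
#' dropped before ranking (standard signed-rank convention); absolute values
#' receive average ranks under ties. The signed z statistic is the plain
#' standardization `(W - E[W]) / sd(W)` with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`. The two-sided p-value is computed
#' by exact enumeration of the sign distribution for `n <= 12` (or when
#' `exact = TRUE`; enumeration is done by dynamic programming over doubled
#' ranks so ties are handled exactly) and from the continuity-corrected
#' normal approximation otherwise (the correction keeps the approximation
#' within about 0.01 of the exact p at n = 16). Under the symmetric exact
#' null, `p = P(|W - E[W]| >= |w - E[W]|)`.
#'
#' @param x numeric vector of, e.g., per-session correlation coefficients.
#' @param mu null median (default 0).
#' @param exact force/forbid exact enumeration; `NULL` enumerates for
#'   `n <= 12` (after dropping zeros).
#' @return list with `statistic` (W+, sum of positive ranks), `n` (non-zero
#'   count), `n_zero` (dropped), `z`, `p`, `defined` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 0, exact = NULL) {
  if (anyNA(x)) stop_data("missing values in signed-rank input")
  d <- x - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, n = 0L, n_zero = n_zero, z = NA_real_,
                p = NA_real_, defined = FALSE, method = "degenerate"))
  }
  if (n < 5L) stop_data("need at least 5 non-zero values, got ", n)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  ties <- table(r)
  var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (var_w <= 0) {
    return(list(statistic = w, n = n, n_zero = n_zero, z = NA_real_,
                p = NA_real_, defined = FALSE, method = "degenerate"))
  }
  z <- (w - e_w) / sqrt(var_w)
  use_exact <- if (is.null(exact)) n <= 12L else isTRUE(exact)
  if (use_exact) {
    r2 <- as.integer(round(2 * r))   # doubled ranks are integers even with ties
    total <- sum(r2)
    f <- numeric(total + 1L)         # f[s + 1] = #sign assignments with 2*W = s
    f[1L] <- 1
    for (v in r2) {
      shifted <- c(numeric(v), f[seq_len(total + 1L - v)])
      f <- f + shifted
    }
    support <- 0:total
    dev <- abs(support - 2 * e_w)
    p <- sum(f[dev >= abs(2 * w - 2 * e_w) - 1e-9]) / 2^n
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-max(abs(w - e_w) - 0.5, 0) / sqrt(var_w))
    method <- "normal"
  }
  list(statistic = w, n = n, n_zero = n_zero, z = z, p = min(p, 1),
       defined = TRUE, method = method)
}

#' Within-session correlations with a group-level signed-rank test
#'
#' For every session, correlates node sizes (local stability of each state)
#' with the node-average value of each variable; sessions with fewer than 3
#' nodes, or with constant sizes or overlays, contribute no coefficient and
#' are listed in `$excluded`. At the group level the per-session
#' coefficients for each variable are tested against median zero with the
#' one-sample signed-rank test; a positive group direction means local
#' stability is high where the variable is high.
#'
#' @param node_tables named list of per-session data.frames as produced by
#'   [node_metrics_table()] (must contain a `size` column plus one column
#'   per variable).
#' @param variables character vector of variable column names.
#' @param min_sessions minimum number of defined coefficients required for a
#'   group test (default 5).
#' @return list with `correlations` (session_id, variable, rho, n_nodes),
#'   `group` (variable, n_sessions, statistic, z, p) and `excluded`
#'   (session_id, variable, reason).
#' @export
within_session_analysis <- function(node_tables, variables, min_sessions = 5L) {
  ids <- names(node_tables) %||% as.character(seq_along(node_tables))
  cors <- list()
  excl <- list()
  for (s in seq_along(node_tables)) {
    tab <- node_tables[[s]]
    sid <- if (!is.null(tab$session_id) && nrow(tab)) as.character(tab$session_id[1L]) else ids[s]
    for (v in variables) {
      if (!v %in% names(tab)) stop_config("variable '", v, "' missing from session ", sid)
      if (nrow(tab) < 3L) {
        excl[[length(excl) + 1L]] <- data.frame(session_id = sid, variable = v,
                                                reason = "fewer than 3 nodes")
        next
      }
      sc <- spearman_cor(tab$size, tab[[v]], p_value = FALSE)
      if (!sc$defined) {
        excl[[length(excl) + 1L]] <- data.frame(session_id = sid, variable = v,
                                                reason = "zero rank variance")
        next
      }
      cors[[length(cors) + 1L]] <- data.frame(session_id = sid, variable = v,
                                              rho = sc$rho, n_nodes = nrow(tab))
    }
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else
    data.frame(session_id = character(), variable = character(),
               rho = numeric(), n_nodes = integer())
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(session_id = character(), variable = character(),
               reason = character())
  group <- lapply(variables, function(v) {
    coeffs <- correlations$rho[correlations$variable == v]
    if (length(coeffs) < min_sessions) {
      warning("variable '", v, "': only ", length(coeffs),
              " defined coefficients (need ", min_sessions, "); group test skipped")
      return(data.frame(variable = v, n_sessions = length(coeffs),
                        statistic = NA_real_, z = NA_real_, p = NA_real_))
    }
    wt <- wilcoxon_signed_rank(coeffs)
    data.frame(variable = v, n_sessions = wt$n + wt$n_zero,
               statistic = wt$statistic, z = wt$z, p = wt$p)
  })
  list(correlations = correlations, group = do.call(rbind, group),
       excluded = excluded)
}

#' Between-session correlations of network features with session averages
#'
#' Spearman correlations, across sessions, of each session-average network
#' feature (mean node size, mean loop length) with each session-average
#' variable. Sessions with an undefined feature (e.g., no defined loop) are
#' excluded pairwise; `n_sessions` reports the pairs actually used.
#'
#' @param summaries data.frame with one row per session as produced by
#'   [summarize_session()] (rbind the rows), containing the feature columns
#'   and `mean_<variable>` columns.
#' @param variables character vector of variable names (without the `mean_`
#'   prefix; a bare column of that name is also accepted).
#' @param features feature columns to correlate (default mean node size and
#'   mean loop length).
#' @param min_sessions minimum paired sessions (default 4).
#' @return data.frame: feature, variable, rho, p, n_sessions, defined.
#' @export
between_session_analysis <- function(summaries, variables,
                                     features = c("mean_node_size",
                                                  "mean_loop_length"),
                                     min_sessions = 4L) {
  rows <- list()
  for (f in features) {
    if (!f %in% names(summaries)) stop_config("feature column '", f, "' missing")
    for (v in variables) {
      col <- if (v %in% names(summaries)) v else paste0("mean_", v)
      if (!col %in% names(summaries)) {
        stop_config("variable column '", v, "' (or 'mean_", v, "') missing")
      }
      ok <- !is.na(summaries[[f]]) & !is.na(summaries[[col]])
      nn <- sum(ok)
      if (nn < min_sessions) {
        stop_data("feature '", f, "' x '", v, "': ", nn,
                  " paired sessions, need >= ", min_sessions)
      }
      sc <- spearman_cor(summaries[[f]][ok], summaries[[col]][ok])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, variable = v, rho = sc$rho, p = sc$p, n_sessions = nn,
        defined = sc$defined)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
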