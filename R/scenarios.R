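#' Grid evaluation of MSEP differences
#'
#' Evaluates, over a factorial grid of scenarios, the difference between
#' the conditional MSEP of each weighted predictor and that of the best
#' predictor. Defaults reproduce the binary-outcome evaluation grid:
#' intercepts -2 and -1; cluster sizes 5, 7, 20, 100; \eqn{\sigma_u} from
#' 0.1 to 1.2 by 0.1 (to 1.0 for Poisson outcomes); thresholds 1.28, 1.645,
#' 1.96, 2.33; SQ weights \eqn{\lambda \in \{0.2, 0.3, 0.4\}} and AB
#' weights \eqn{\lambda \in \{1.2, 1.6, 2.0\}}. Cells where a weighted
#' integral diverges are recorded with `divergent = TRUE`, not dropped.
#'
#' @param family Family name or [glmm_family()] object.
#' @param mu,n,sigma_u,tau Grid vectors (intercept, cluster size,
#'   random-effect scale, extremeness threshold).
#' @param weights Data frame with columns `kind` and `lambda`, one row per
#'   weighted predictor.
#' @param tail Conditioning tail passed to [msep()].
#' @param n_nodes,pred_nodes Bounded-quadrature and posterior-quadrature
#'   node counts.
#' @param verbose Emit a progress line every 100 cells.
#' @return A data frame with one row per scenario x predictor: the grid
#'   coordinates, `kind`, `lambda`, `msep`, `msep_bp`, `diff`, `divergent`.
#' @examples
#' run_msep_grid("bernoulli_logit", mu = -1, n = 7, sigma_u = 0.5,
#'               tau = 1.28)
#' @export
run_msep_grid <- function(family = "bernoulli_logit",
                          mu = c(-2, -1),
                          n = c(5, 7, 20, 100),
                          sigma_u = NULL,
                          tau = c(1.28, 1.645, 1.96, 2.33),
                          weights = default_msep_weights(),
                          tail = "upper", n_nodes = 64L, pred_nodes = 64L,
                          verbose = FALSE) {
  if (is.character(family)) family <- glmm_family(family)
  if (is.null(sigma_u))
    sigma_u <- seq(0.1, if (family$name == "poisson_log") 1.0 else 1.2, by = 0.1)
  cells <- expand.grid(mu = mu, n = n, sigma_u = sigma_u, tau = tau,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$mu, cells$n, cells$sigma_u, cells$tau), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    bp <- zpredictor(family, sigma_u = cl$sigma_u, n = cl$n, mu = cl$mu,
                     n_nodes = pred_nodes)
    m_bp <- msep(bp, cl$tau, tail, n_nodes)$msep
    rows <- lapply(seq_len(nrow(weights)), function(j) {
      w <- weight_spec(as.character(weights$kind[j]), weights$lambda[j])
      m_w <- tryCatch(msep(set_weight(bp, w), cl$tau, tail, n_nodes)$msep,
                      error = function(e) NA_real_)
      data.frame(family = family$name, mu = cl$mu, n = cl$n,
                 sigma_u = cl$sigma_u, tau = cl$tau,
                 kind = w$kind, lambda = w$lambda,
                 msep = m_w, msep_bp = m_bp, diff = m_w - m_bp,
                 divergent = is.na(m_w))
    })
    out[[i]] <- do.call(rbind, rows)
    if (verbose && i %% 100 == 0)
      message(sprintf("msep grid: %d / %d cells", i, nrow(cells)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname run_msep_grid
#' @export
default_msep_weights <- function() {
  data.frame(kind = rep(c("SQ", "AB"), each = 3),
             lambda = c(0.2, 0.3, 0.4, 1.2, 1.6, 2.0))
}

#' Grid evaluation of incorrect and correct flagging rates
#'
#' For every scenario cell, computes the best predictor's exact incorrect
#' and correct flagging rates, marks the cell infeasible when the BP rule
#' already exceeds the nominal \eqn{\alpha} (the discreteness of the
#' cluster total then rules out any self-calibrated predictor), and in
#' feasible cells self-calibrates the requested weight families and
#' records their exact rates. Defaults reproduce the binary-outcome
#' flagging grid: intercepts -1 to 1 by 0.5, cluster sizes 5, 10, 20, 100,
#' thresholds 1.28, 1.645, 1.96, 2.33, \eqn{\sigma_u} from 0.1 to 1.3 by
#' 0.1 (13 values, 2080 scenario cells over both \eqn{\alpha}), and
#' \eqn{\alpha \in \{0.05, 0.1\}}.
#'
#' A cell is infeasible when no self-calibrated predictor exists there:
#' either the BP rule's incorrect rate already exceeds \eqn{\alpha}, or
#' the conditional quantile \eqn{y_\alpha} sits at the support maximum so
#' that only the empty flag set would comply (see [calibrate()]). The BP
#' rows always carry the plain "flag when \eqn{\tilde z_{BP} > \tau}"
#' rates - zero when the best predictor cannot reach \eqn{\tau} anywhere
#' in the support.
#'
#' @inheritParams run_msep_grid
#' @param alpha Nominal incorrect flagging rates.
#' @param weights Character vector of weight families to calibrate.
#' @return A data frame with one row per scenario x alpha x predictor
#'   (`BP` plus each calibrated family): grid coordinates, `predictor`,
#'   `lambda`, `y_alpha`, `threshold_y`, `incorrect`, `correct`,
#'   `feasible`, `exact_boundary`.
#' @examples
#' run_flagging_grid("bernoulli_logit", mu = 0, n = 20, sigma_u = 0.6,
#'                   tau = 1.28, alpha = 0.1)
#' @export
run_flagging_grid <- function(family = "bernoulli_logit",
                              mu = c(-1, -0.5, 0, 0.5, 1),
                              n = c(5, 10, 20, 100),
                              sigma_u = seq(0.1, 1.3, by = 0.1),
                              tau = c(1.28, 1.645, 1.96, 2.33),
                              alpha = c(0.05, 0.1),
                              weights = c("SQ", "AB"),
                              n_nodes = 64L, pred_nodes = 64L,
                              verbose = FALSE) {
  if (is.character(family)) family <- glmm_family(family)
  cells <- expand.grid(mu = mu, n = n, sigma_u = sigma_u, tau = tau,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$mu, cells$n, cells$sigma_u, cells$tau), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    ctx <- zpredictor(family, sigma_u = cl$sigma_u, n = cl$n, mu = cl$mu,
                      n_nodes = pred_nodes)
    tailp <- make_tailp(ctx, cl$tau, n_nodes)
    thr_bp <- invert_threshold(ctx, cl$tau)
    bp_rates <- flag_rates(ctx, cl$tau, threshold = thr_bp, n_nodes = n_nodes)
    sup_max <- if (family$name %in% c("bernoulli_logit", "binomial_logit"))
      cl$n else Inf
    rows <- list()
    for (a in alpha) {
      y_a <- y_alpha_search(ctx, tailp, a)
      feasible <- bp_rates$incorrect <= a + 1e-12 && y_a < sup_max
      meta <- data.frame(family = family$name, mu = cl$mu, n = cl$n,
                         sigma_u = cl$sigma_u, tau = cl$tau, alpha = a)
      rows[[length(rows) + 1L]] <- cbind(meta, data.frame(
        predictor = "BP", lambda = 0, y_alpha = as.numeric(y_a),
        threshold_y = thr_bp, incorrect = bp_rates$incorrect,
        correct = bp_rates$correct, feasible = feasible,
        exact_boundary = NA))
      for (kind in weights) {
        if (feasible) {
          cal <- calibrate_core(ctx, kind, cl$tau, a,
                                if (kind == "SQ") c(0, 0.49) else c(0, 8),
                                n_nodes, tailp, thr_bp)
          rows[[length(rows) + 1L]] <- cbind(meta, data.frame(
            predictor = kind, lambda = cal$lambda_star,
            y_alpha = as.numeric(cal$y_alpha),
            threshold_y = as.numeric(cal$threshold_y),
            incorrect = cal$achieved_incorrect,
            correct = cal$achieved_correct, feasible = TRUE,
            exact_boundary = cal$exact_boundary))
        } else {
          rows[[length(rows) + 1L]] <- cbind(meta, data.frame(
            predictor = kind, lambda = NA_real_, y_alpha = NA_real_,
            threshold_y = NA_real_, incorrect = NA_real_,
            correct = NA_real_, feasible = FALSE, exact_boundary = NA))
        }
      }
    }
    out[[i]] <- do.call(rbind, rows)
    if (verbose && i %% 100 == 0)
      message(sprintf("flagging grid: %d / %d cells", i, nrow(cells)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box-plot summary statistics of a grid result table
#'
#' Median, quartiles and whiskers (as drawn by a standard box plot) of a
#' result column, by predictor and any further grouping columns, computed
#' over feasible rows only - infeasible scenarios are excluded the same way
#' the evaluation excludes them.
#'
#' @param table A result table from [run_flagging_grid()] or
#'   [run_msep_grid()].
#' @param value Name of the value column (e.g. `"incorrect"`, `"correct"`,
#'   `"diff"`).
#' @param by Grouping column names present in `table`.
#' @param digits Rounding applied to the summary statistics (default 2, the
#'   precision at which grid summaries are reported).
#' @return A data frame of group keys plus `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`. A table with no feasible rows yields a
#'   zero-row frame carrying attribute `empty = TRUE`.
#' @export
summarize_grid <- function(table, value = "incorrect",
                           by = intersect(c("predictor", "kind", "lambda", "alpha"),
                                          names(table)),
                           digits = 2) {
  if (!value %in% names(table)) stop(sprintf("no column '%s' in table", value))
  keep <- if ("feasible" %in% names(table)) isTRUE_vec(table$feasible) else
    rep(TRUE, nrow(table))
  keep <- keep & !is.na(table[[value]])
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(numeric(0), 0, length(by) + 6)),
      c(by, "n", "median", "q1", "q3", "whisker_lo", "whisker_hi"))
    attr(out, "empty") <- TRUE
    return(out)
  }
  groups <- split(seq_len(nrow(tab)), tab[by], drop = TRUE)
  rows <- lapply(groups, function(idx) {
    x <- tab[[value]][idx]
    bs <- grDevices::boxplot.stats(x)$stats
    cbind(tab[idx[1L], by, drop = FALSE],
          data.frame(n = length(x),
                     median = round(bs[3], digits),
                     q1 = round(bs[2], digits), q3 = round(bs[4], digits),
                     whisker_lo = round(bs[1], digits),
                     whisker_hi = round(bs[5], digits)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read and write grid tables and run configurations
#'
#' Grid results travel as comma-delimited text with a header row;
#' configurations are YAML files whose keys mirror the arguments of
#' [run_msep_grid()] and [run_flagging_grid()].
#'
#' @param table A grid result data frame.
#' @param path File path.
#' @return `read_grid()` returns the data frame; `write_grid()` its path,
#'   invisibly. `read_run_config()` returns the named list of settings.
#' @export
write_grid <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) utils::read.csv(path)

#' @rdname write_grid
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  yaml::read_yaml(path)
}
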