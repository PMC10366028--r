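# Ordinary-least-squares fits and stepwise AIC model selection.
#
# Selection is greedy on the Gaussian AIC (full log-likelihood including
# constants, counting the residual-variance parameter), in three directions:
# forward (add the term giving the largest AIC decrement, from the null
# model), backward (remove analogously, from the full model) and combination
# (forward moves plus one-out/one-in swaps). Ties are broken toward fewer
# terms, then lexicographically by term label, so selection is deterministic.

fit_lm_terms <- function(data, dv, terms) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste(dv, "~", rhs))
  stats::lm(f, data = data)
}

#' Fit an ordinary least squares model
#'
#' @param data Data frame.
#' @param dv Dependent-variable column name.
#' @param terms Character vector of independent-variable terms; interaction
#'   terms are written `"a:b"` and should be accompanied by their main
#'   effects. Empty for the intercept-only model.
#' @return An `epeli_lm_fit`: coefficient table (estimate, SE, t, two-sided
#'   p), R-squared, adjusted R-squared, AIC (Gaussian, equal to
#'   `n*log(2*pi*RSS/n) + n + 2*(p_coef + 1)` with the intercept counted in
#'   `p_coef` and the `+1` for the variance parameter), and the underlying
#'   `lm` fit.
#' @export
fit_ols <- function(data, dv, terms = character()) {
  fit <- fit_lm_terms(data, dv, terms)
  if (anyNA(stats::coef(fit))) {
    stop_epelir("rank-deficient design (aliased coefficients)",
                "epelir_structure_error")
  }
  n <- stats::nobs(fit)
  if (n <= length(stats::coef(fit))) {
    stop_epelir("more parameters than observations", "epelir_structure_error")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    dv = dv, terms = terms,
    coefficients = fast_df(list(term = rownames(ct),
                                estimate = unname(ct[, 1L]),
                                se = unname(ct[, 2L]), t = unname(ct[, 3L]),
                                p = unname(ct[, 4L]))),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    aic = stats::AIC(fit),
    n = n,
    fit = fit), class = "epeli_lm_fit")
}

#' @export
print.epeli_lm_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s\n", x$dv,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  print.data.frame(x$coefficients, digits = 4, row.names = FALSE)
  cat(sprintf("n = %d, R^2 = %.3f, adj. R^2 = %.3f, AIC = %.2f\n",
              x$n, x$r_squared, x$adj_r_squared, x$aic))
  invisible(x)
}

#' @export
coef.epeli_lm_fit <- function(object, ...) stats::coef(object$fit)

aic_of <- function(data, dv, terms) stats::AIC(fit_lm_terms(data, dv, terms))

# candidate moves for one step; each is list(terms, aic, action, added,
# removed, n_terms)
step_moves <- function(data, dv, current, candidates, direction) {
  moves <- list()
  addable <- setdiff(candidates, current)
  if (direction %in% c("forward", "combination")) {
    for (tm in addable) {
      nt <- c(current, tm)
      moves[[length(moves) + 1L]] <- list(terms = nt, aic = aic_of(data, dv, nt),
                                          action = "add", added = tm,
                                          removed = NA_character_)
    }
  }
  if (direction == "backward") {
    for (tm in current) {
      nt <- setdiff(current, tm)
      moves[[length(moves) + 1L]] <- list(terms = nt, aic = aic_of(data, dv, nt),
                                          action = "remove",
                                          added = NA_character_, removed = tm)
    }
  }
  if (direction == "combination") {
    for (out in current) {
      for (inn in addable) {
        nt <- c(setdiff(current, out), inn)
        moves[[length(moves) + 1L]] <- list(terms = nt,
                                            aic = aic_of(data, dv, nt),
                                            action = "swap", added = inn,
                                            removed = out)
      }
    }
  }
  moves
}

pick_move <- function(moves) {
  aics <- vapply(moves, `[[`, 0, "aic")
  best <- min(aics)
  tied <- which(aics <= best + 1e-9)
  if (length(tied) > 1L) {
    sizes <- vapply(moves[tied], function(m) length(m$terms), 1L)
    tied <- tied[sizes == min(sizes)]
    if (length(tied) > 1L) {
      labs <- vapply(moves[tied], function(m) {
        paste(m$added %||% "", m$removed %||% "")
      }, "")
      tied <- tied[order(labs)]
    }
  }
  moves[[tied[1L]]]
}

#' Stepwise AIC model selection
#'
#' @param data Data frame.
#' @param dv Dependent-variable column name.
#' @param candidates Character vector of candidate terms (at most 12, so an
#'   exhaustive check stays feasible).
#' @param direction `"forward"` (start from the null model, add the term
#'   with the largest AIC decrement until none decreases it), `"backward"`
#'   (start full, remove analogously) or `"combination"` (forward moves plus
#'   one-out/one-in swaps).
#' @return An `epeli_stepwise`: list with `direction`, `start_aic`, `steps`
#'   (data frame: action, term added/removed, AIC after the step — strictly
#'   decreasing), `final` (an `epeli_lm_fit`), `final_aic`, `final_terms`.
#' @export
stepwise_select <- function(data, dv, candidates,
                            direction = c("forward", "backward", "combination")) {
  direction <- match.arg(direction)
  if (length(candidates) > 12L) {
    stop_epelir("at most 12 candidate terms supported", "epelir_structure_error")
  }
  current <- if (direction == "backward") candidates else character()
  cur_aic <- aic_of(data, dv, current)
  start_aic <- cur_aic
  steps <- list()
  repeat {
    moves <- step_moves(data, dv, current, candidates, direction)
    if (length(moves) == 0L) break
    mv <- pick_move(moves)
    if (mv$aic >= cur_aic - 1e-9) break
    current <- mv$terms
    cur_aic <- mv$aic
    steps[[length(steps) + 1L]] <- fast_df(list(
      action = mv$action, term_added = mv$added, term_removed = mv$removed,
      aic = mv$aic))
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    fast_df(list(action = character(), term_added = character(),
                 term_removed = character(), aic = numeric()))
  structure(list(direction = direction, start_aic = start_aic, steps = steps,
                 final = fit_ols(data, dv, sort(current)),
                 final_aic = cur_aic, final_terms = sort(current)),
            class = "epeli_stepwise")
}

#' @export
print.epeli_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise selection (%s): AIC %.2f -> %.2f in %d step(s)\n",
              x$direction, x$start_aic, x$final_aic, nrow(x$steps)))
  cat(sprintf("  final model: %s\n",
              if (length(x$final_terms)) paste(x$final_terms, collapse = " + ")
              else "(null)"))
  invisible(x)
}

#' Choose the best of several stepwise paths
#'
#' The path with the lowest final AIC wins; ties go to the path with fewer
#' terms, then to the earlier path in the list.
#'
#' @param paths List of `epeli_stepwise` objects.
#' @return One `epeli_stepwise`.
#' @export
pick_best_of_directions <- function(paths) {
  if (length(paths) == 0L) stop_epelir("empty path list", "epelir_structure_error")
  aics <- vapply(paths, `[[`, 0, "final_aic")
  best <- which(aics <= min(aics) + 1e-9)
  if (length(best) > 1L) {
    sizes <- vapply(paths[best], function(p) length(p$final_terms), 1L)
    best <- best[sizes == min(sizes)]
  }
  paths[[best[1L]]]
}
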