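# Nonlinear least squares engines for the two-step fitting procedure.
# Stage 1 fits the Fermi sigmoid at each pulse number; stage 2 fits the
# exponential pulse-number dependence of its two parameters.

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

# Fit S = 1/(1 + exp((E - ec)/ac)) to (efs, survival-fraction) pairs.
# Initial guess: ec at the field whose survival is nearest 0.5,
# ac = field range / 4; grid multi-start on failure.
fit_fermi_curve <- function(efs, s) {
  stopifnot(length(efs) == length(s))
  if (length(unique(efs)) < 3) {
    abort("Need at least 3 distinct field strengths.",
          class = "ebtsim_insufficient_design")
  }
  # average duplicated field levels before fitting
  d <- tibble::tibble(efs = efs, s = s) |>
    dplyr::group_by(.data$efs) |>
    dplyr::summarise(s = mean(.data$s), .groups = "drop")
  if (sd(d$s) == 0) {
    abort("Constant survival across field strengths; sigmoid fit is degenerate.",
          class = "ebtsim_fit_failure")
  }
  span <- diff(range(d$efs))
  starts <- list(c(ec = d$efs[which.min(abs(d$s - 0.5))], ac = span / 4))
  for (ec0 in stats::quantile(d$efs, c(0.25, 0.5, 0.75), names = FALSE)) {
    for (ac0 in span * c(0.1, 0.25, 0.5)) {
      starts <- c(starts, list(c(ec = ec0, ac = ac0)))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ 1 / (1 + exp((efs - ec) / ac)),
        data = d, start = as.list(st),
        lower = c(ec = 1e-6, ac = 1e-6), upper = c(ec = 1e5, ac = 1e5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Sigmoid fit failed to converge from all starts.",
          class = "ebtsim_fit_failure")
  }
  cf <- coef(best$fit)
  list(ec = unname(cf["ec"]), ac = unname(cf["ac"]),
       r2 = r_squared(d$s, stats::fitted(best$fit)),
       n_points = nrow(d))
}

# Fit y = A * exp(-k * n). Initialised by log-linear regression on positive
# values, with a fallback grid of decay rates (amplitude then closed-form);
# k is allowed to be negative (bounded to [-0.1, 0.1]).
fit_exp_decay <- function(n, y) {
  stopifnot(length(n) == length(y))
  if (length(unique(n)) < 3) {
    abort("Need at least 3 distinct pulse numbers.",
          class = "ebtsim_insufficient_design")
  }
  d <- tibble::tibble(n = n, y = y)
  starts <- list()
  if (all(y > 0)) {
    ll <- lm(log(y) ~ n, data = d)
    starts <- list(c(a = exp(unname(coef(ll)[1])),
                     k = -unname(coef(ll)[2])))
  }
  for (k0 in seq(-0.02, 0.05, by = 0.01)) {
    b <- exp(-k0 * d$n)
    a0 <- sum(d$y * b) / sum(b^2)   # least-squares amplitude at fixed k
    if (is.finite(a0) && a0 > 0) starts <- c(starts, list(c(a = a0, k = k0)))
  }
  best <- NULL
  for (st in starts) {
    st["k"] <- min(max(st[["k"]], -0.1), 0.1)
    st["a"] <- min(max(st[["a"]], 1e-6), 1e5)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-k * n), data = d, start = as.list(st),
        lower = c(a = 1e-6, k = -0.1), upper = c(a = 1e5, k = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Exponential fit failed to converge from all starts.",
          class = "ebtsim_fit_failure")
  }
  cf <- coef(best$fit)
  list(a = unname(cf["a"]), k = unname(cf["k"]),
       r2 = r_squared(d$y, stats::fitted(best$fit)))
}

#' Stage 1: fit the survival sigmoid at each pulse number
#'
#' For one cell line and pulse duration, fits the Fermi sigmoid to mean
#' viability (as a fraction) versus field strength, separately for each
#' pulse number, yielding the half-lethality field \eqn{E_c(N)} and slope
#' constant \eqn{A_c(N)} with a per-fit \eqn{R^2}. By default replicate
#' means are fitted; set `use_replicates = "all"` to fit every replicate
#' point instead.
#'
#' @param data A viability tibble (percent scale; see [read_viability()]).
#' @param cell_line,pulse_duration_us Which block of the dataset to fit.
#' @param pulse_numbers Pulse numbers to fit; default all present.
#' @param use_replicates `"means"` (default) or `"all"`.
#' @return A tibble of class `ep_stage1` with columns `cell_line`, `organ`,
#'   `pulse_duration_us`, `pulse_number`, `ec_n`, `ac_n`, `r2`, `n_points`.
#' @export
fit_stage1 <- function(data, cell_line, pulse_duration_us,
                       pulse_numbers = NULL,
                       use_replicates = c("means", "all")) {
  use_replicates <- match.arg(use_replicates)
  cl <- cell_line
  dur <- pulse_duration_us
  block <- dplyr::filter(data, .data$cell_line == cl,
                         .data$pulse_duration_us == dur)
  if (nrow(block) == 0) {
    abort(paste0("No data for ", cl, " at ", dur, " us."),
          class = "ebtsim_validation_error")
  }
  if (is.null(pulse_numbers)) pulse_numbers <- sort(unique(block$pulse_number))
  organ <- block$organ[1]
  fits <- purrr::map(pulse_numbers, function(np) {
    sub <- dplyr::filter(block, .data$pulse_number == np)
    if (use_replicates == "means") {
      sub <- dplyr::group_by(sub, .data$efs_v_cm) |>
        dplyr::summarise(viability_pct = mean(.data$viability_pct),
                         .groups = "drop")
    }
    f <- fit_fermi_curve(sub$efs_v_cm, sub$viability_pct / 100)
    tibble::tibble(cell_line = cl, organ = organ, pulse_duration_us = dur,
                   pulse_number = np, ec_n = f$ec, ac_n = f$ac, r2 = f$r2,
                   n_points = f$n_points)
  })
  out <- dplyr::bind_rows(fits)
  class(out) <- c("ep_stage1", class(out))
  out
}

#' Stage 2: fit the exponential pulse-number dependence
#'
#' Fits \eqn{E_c(N) = E_0 e^{-k_1 N}} to the stage-1 half-lethality fields
#' and, as a separate least-squares problem, \eqn{A_c(N) = A_0 e^{-k_2 N}}
#' to the stage-1 slope constants; each fit carries its own \eqn{R^2}.
#' Rate constants may come out negative.
#'
#' @param stage1 A stage-1 tibble from [fit_stage1()] (needs >= 3 distinct
#'   pulse numbers).
#' @return A one-row coefficient tibble with columns `cell_line`, `organ`,
#'   `pulse_duration_us`, `e0`, `k1`, `r2_e`, `a0`, `k2`, `r2_a`,
#'   `n_stage1`.
#' @export
fit_stage2 <- function(stage1) {
  fe <- fit_exp_decay(stage1$pulse_number, stage1$ec_n)
  fa <- fit_exp_decay(stage1$pulse_number, stage1$ac_n)
  tibble::tibble(
    cell_line = stage1$cell_line[1] %||% NA_character_,
    organ = stage1$organ[1] %||% NA_character_,
    pulse_duration_us = stage1$pulse_duration_us[1] %||% NA_real_,
    e0 = fe$a, k1 = fe$k, r2_e = fe$r2,
    a0 = fa$a, k2 = fa$k, r2_a = fa$r2,
    n_stage1 = nrow(stage1)
  )
}

#' Two-step Peleg-Fermi fit
#'
#' Orchestrates the full procedure over every (cell line, pulse duration)
#' block present in `data` (or the subset requested): a stage-1 sigmoid fit
#' per pulse number, then the stage-2 exponential fits of \eqn{E_c(N)} and
#' \eqn{A_c(N)}. Pulse numbers whose stage-1 fit fails are dropped with a
#' warning; a block needs at least 3 surviving pulse numbers.
#'
#' @param data A viability tibble.
#' @param cell_line,pulse_duration_us Optional filters (default: all blocks).
#' @param use_replicates Passed to [fit_stage1()].
#' @return An object of class `ep_pf_fit`: a list with `coefficients`
#'   (one row per fitted block), `stage1` (all per-pulse-number fits) and
#'   `failures` (blocks or pulse numbers that could not be fitted).
#'   Use [tidy()] / [glance()] to extract tables.
#' @export
fit_peleg_fermi <- function(data, cell_line = NULL, pulse_duration_us = NULL,
                            use_replicates = c("means", "all")) {
  use_replicates <- match.arg(use_replicates)
  blocks <- dplyr::distinct(data, .data$cell_line, .data$pulse_duration_us)
  if (!is.null(cell_line)) {
    blocks <- dplyr::filter(blocks, .data$cell_line %in% !!cell_line)
  }
  if (!is.null(pulse_duration_us)) {
    blocks <- dplyr::filter(blocks,
                            .data$pulse_duration_us %in% !!pulse_duration_us)
  }
  if (nrow(blocks) == 0) {
    abort("No matching (cell_line, pulse_duration_us) blocks.",
          class = "ebtsim_validation_error")
  }
  coefs <- list(); stage1_all <- list(); failures <- list()
  for (b in seq_len(nrow(blocks))) {
    cl <- blocks$cell_line[b]; dur <- blocks$pulse_duration_us[b]
    pns <- sort(unique(
      dplyr::filter(data, .data$cell_line == cl,
                    .data$pulse_duration_us == dur)$pulse_number
    ))
    per_n <- purrr::map(pns, function(np) {
      tryCatch(
        fit_stage1(data, cl, dur, pulse_numbers = np,
                   use_replicates = use_replicates),
        error = function(e) {
          failures[[length(failures) + 1]] <<- tibble::tibble(
            cell_line = cl, pulse_duration_us = dur, pulse_number = np,
            stage = "stage1", message = conditionMessage(e))
          NULL
        }
      )
    })
    s1 <- dplyr::bind_rows(per_n)
    if (nrow(s1) < length(pns)) {
      warn(paste0(cl, "/", dur, " us: stage-1 failed for ",
                  length(pns) - nrow(s1), " pulse number(s); fitting on ",
                  nrow(s1), "."))
    }
    if (nrow(s1) < 3) {
      failures[[length(failures) + 1]] <- tibble::tibble(
        cell_line = cl, pulse_duration_us = dur, pulse_number = NA_real_,
        stage = "stage2", message = "fewer than 3 successful stage-1 fits")
      next
    }
    stage1_all[[length(stage1_all) + 1]] <- s1
    coefs[[length(coefs) + 1]] <- fit_stage2(s1)
  }
  if (length(coefs) == 0) {
    abort("All blocks failed to fit.", class = "ebtsim_fit_failure")
  }
  structure(
    list(coefficients = dplyr::bind_rows(coefs),
         stage1 = dplyr::bind_rows(stage1_all),
         failures = dplyr::bind_rows(failures)),
    class = "ep_pf_fit"
  )
}

#' @export
print.ep_pf_fit <- function(x, ...) {
  cat("Two-step Peleg-Fermi fit:", nrow(x$coefficients),
      "coefficient set(s)\n")
  print(x$coefficients)
  if (nrow(x$failures) > 0) {
    cat("Failures:", nrow(x$failures), "(see $failures)\n")
  }
  invisible(x)
}

# double-exponential fit used by the modified model; multi-start around the
# single-exponential solution plus rate-splitting perturbations
fit_double_exp <- function(n, y) {
  d <- tibble::tibble(n = n, y = y)
  single <- tryCatch(fit_exp_decay(n, y), error = function(e) NULL)
  starts <- list()
  if (!is.null(single)) {
    for (split in c(0.5, 0.25, 0.75)) {
      for (fac in c(2, 5)) {
        starts <- c(starts, list(c(
          c1 = single$a * split, r1 = min(single$k * fac, 0.1),
          c2 = single$a * (1 - split), r2 = single$k / fac)))
      }
    }
  }
  starts <- c(starts, list(
    c(c1 = max(y) / 2, r1 = 0.02, c2 = max(y) / 2, r2 = 0.002),
    c(c1 = max(y), r1 = 0.01, c2 = min(y) / 2, r2 = 0)
  ))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c1 * exp(-r1 * n) + c2 * exp(-r2 * n), data = d,
        start = as.list(st),
        lower = c(c1 = 0, r1 = -0.1, c2 = 0, r2 = -0.1),
        upper = c(c1 = 1e5, r1 = 0.1, c2 = 1e5, r2 = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Double-exponential fit failed from all starts.",
          class = "ebtsim_fit_failure")
  }
  cf <- coef(best$fit)
  list(c1 = unname(cf["c1"]), r1 = unname(cf["r1"]),
       c2 = unname(cf["c2"]), r2 = unname(cf["r2"]),
       r2_stat = r_squared(d$y, stats::fitted(best$fit)))
}

#' Modified (double-exponential) Peleg-Fermi fit
#'
#' Fallback for datasets whose \eqn{E_c(N)} or \eqn{A_c(N)} sequence is not
#' well described by a single exponential:
#' \eqn{E_c(N) = E_1 e^{-k_1 N} + E_2 e^{-k_2 N}} and likewise
#' \eqn{A_c(N) = A_1 e^{-k_3 N} + A_2 e^{-k_4 N}}. The two exponential
#' terms are exchangeable, so downstream comparisons should be made on
#' predicted curves, not on individual coefficients.
#'
#' @param stage1 A stage-1 tibble with at least 5 distinct pulse numbers
#'   (4 parameters per curve).
#' @return A one-row tibble of class `ep_modified_fit` with columns
#'   `e1`, `k1`, `e2`, `k2`, `r2_e`, `a1`, `k3`, `a2`, `k4`, `r2_a`.
#' @export
fit_modified_peleg_fermi <- function(stage1) {
  if (length(unique(stage1$pulse_number)) < 5) {
    abort("Modified model needs >= 5 distinct pulse numbers.",
          class = "ebtsim_insufficient_design")
  }
  fe <- fit_double_exp(stage1$pulse_number, stage1$ec_n)
  fa <- fit_double_exp(stage1$pulse_number, stage1$ac_n)
  out <- tibble::tibble(
    cell_line = stage1$cell_line[1] %||% NA_character_,
    organ = stage1$organ[1] %||% NA_character_,
    pulse_duration_us = stage1$pulse_duration_us[1] %||% NA_real_,
    e1 = fe$c1, k1 = fe$r1, e2 = fe$c2, k2 = fe$r2, r2_e = fe$r2_stat,
    a1 = fa$c1, k3 = fa$r1, a2 = fa$c2, k4 = fa$r2, r2_a = fa$r2_stat
  )
  class(out) <- c("ep_modified_fit", class(out))
  out
}

#' Power-law field-duration model
#'
#' Fits \eqn{E = a\,(t_p / t_0)^b} with \eqn{t_0 = 1} ms fixed, by ordinary
#' least squares in log-log coordinates. Exact on any two-point input. Used
#' to relate a characteristic lethal field (by convention \eqn{E_c(100)})
#' to pulse duration when the Peleg-Fermi fits are unavailable.
#'
#' @param duration_ms Pulse durations in milliseconds (>= 2 distinct).
#' @param field_v_cm Positive characteristic field strengths, V/cm.
#' @return A one-row tibble with `a` (V/cm), `b` (exponent), `t0_ms` = 1,
#'   and the log-log `r2`.
#' @export
fit_power_law <- function(duration_ms, field_v_cm) {
  if (any(field_v_cm <= 0) || any(duration_ms <= 0)) {
    abort("Durations and fields must be positive.",
          class = "ebtsim_domain_error")
  }
  if (length(unique(duration_ms)) < 2) {
    abort("Need at least 2 distinct durations.",
          class = "ebtsim_insufficient_design")
  }
  ll <- lm(log(field_v_cm) ~ log(duration_ms))
  fitted_log <- stats::fitted(ll)
  tibble::tibble(
    a = exp(unname(coef(ll)[1])), b = unname(coef(ll)[2]), t0_ms = 1,
    r2 = if (length(duration_ms) > 2) r_squared(log(field_v_cm), fitted_log)
         else 1
  )
}
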