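# 1:1 Langmuir binding kinetics for biolayer-interferometry sensorgrams:
# model response, simulation, global least-squares fitting across analyte
# concentrations (shared ka, kd, Rmax), and the KD = kd/ka identity.

#' 1:1 binding model response
#'
#' Association (analyte concentration `C`, time from injection):
#' `R(t) = Req * (1 - exp(-(ka*C + kd) * t))` with
#' `Req = Rmax * C / (C + KD)`, `KD = kd/ka`. Dissociation (time measured
#' from the end of association at `t_assoc`):
#' `R(t) = R(t_assoc) * exp(-kd * t)`.
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param Rmax Maximum response (response units).
#' @param conc Analyte concentration in M (>= 0).
#' @param time Time in s: within-phase time (>= 0).
#' @param phase `"association"` or `"dissociation"`.
#' @param t_assoc Association duration in s (needed for dissociation).
#' @return Numeric response values.
#' @export
bli_response <- function(ka, kd, Rmax, conc, time,
                         phase = c("association", "dissociation"),
                         t_assoc = 120) {
  phase <- match.arg(phase)
  stopifnot(ka > 0, kd >= 0, Rmax >= 0, all(time >= 0))
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  KD <- kd / ka
  req <- ifelse(conc + KD == 0, 0, Rmax * conc / (conc + KD))
  r_assoc_end <- req * (1 - exp(-(ka * conc + kd) * t_assoc))
  if (phase == "association") {
    req * (1 - exp(-(ka * conc + kd) * time))
  } else {
    r_assoc_end * exp(-kd * time)
  }
}

#' Simulate noisy BLI sensorgrams
#'
#' Samples the 1:1 model at a fixed rate over a 2-min association and 3-min
#' dissociation phase (the instrument protocol defaults) and adds i.i.d.
#' Gaussian noise.
#'
#' @inheritParams bli_response
#' @param concentrations Analyte concentrations in M (include 0 for a
#'   reference curve; at least two distinct positive values are needed for
#'   an identifiable global fit).
#' @param t_assoc,t_dissoc Phase durations in s.
#' @param rate Sampling rate in Hz.
#' @param noise_sd Gaussian noise SD in response units.
#' @param seed Top-level seed (sub-stream `"sensorgram"`).
#' @return A tibble: `conc`, `phase`, `time` (within-phase, s), `response`.
#' @export
sim_sensorgrams <- function(ka, kd, Rmax, concentrations,
                            t_assoc = 120, t_dissoc = 180, rate = 5,
                            noise_sd = 0, seed = 1) {
  stopifnot(length(concentrations) >= 1, noise_sd >= 0)
  with_substream(seed, "sensorgram", {
    out <- lapply(concentrations, function(C) {
      ta <- seq(0, t_assoc, by = 1 / rate)
      td <- seq(1 / rate, t_dissoc, by = 1 / rate)
      resp <- c(bli_response(ka, kd, Rmax, C, ta, "association", t_assoc),
                bli_response(ka, kd, Rmax, C, td, "dissociation", t_assoc))
      tibble::tibble(
        conc = C,
        phase = rep(c("association", "dissociation"),
                    c(length(ta), length(td))),
        time = c(ta, td),
        response = resp + rnorm(length(resp), 0, noise_sd)
      )
    })
    dplyr::bind_rows(out)
  })
}

# initial kd from a log-linear regression of the dissociation tail of the
# highest-concentration curve
init_kd <- function(data) {
  top <- data[data$conc == max(data$conc) & data$phase == "dissociation", ]
  tail_part <- top[top$time >= median(top$time) & top$response > 0, ]
  if (nrow(tail_part) < 3) return(1e-2)
  fit <- lm(log(tail_part$response) ~ tail_part$time)
  kd0 <- -coef(fit)[[2]]
  if (!is.finite(kd0) || kd0 <= 0) 1e-2 else kd0
}

#' Global 1:1 fit of BLI sensorgrams
#'
#' Least-squares fit of shared (ka, kd, Rmax) across all curves, on log
#' scale for positivity, minimized with Levenberg-Marquardt. The
#' 0-concentration curve, when present, is subtracted as a reference
#' baseline (matched by phase and time). Initialization: kd from a
#' log-linear regression of the dissociation tail of the
#' highest-concentration curve, ka = 1e5 /(M s), Rmax = 1.5 x the maximum
#' observed response; convergence when the relative parameter change drops
#' below 1e-9 (at most 500 iterations).
#'
#' @param data Sensorgram tibble (`conc` in M, `phase`, `time`, `response`),
#'   e.g. from [sim_sensorgrams()] or read from CSV.
#' @param t_assoc Association duration in s.
#' @return A `bli_fit` object: list with `ka`, `kd`, `KD` (M), `KD_nM`,
#'   `Rmax`, `rss`, `req` (per-concentration plateau tibble), `converged`,
#'   `niter`, `data` (baseline-subtracted) and `fitted`.
#' @export
bli_global_fit <- function(data, t_assoc = 120) {
  stopifnot(all(c("conc", "phase", "time", "response") %in% names(data)))
  pos <- sort(unique(data$conc[data$conc > 0]))
  if (length(pos) < 2) {
    stop("global fitting needs at least two distinct positive ",
         "concentrations", call. = FALSE)
  }
  if (any(data$conc == 0)) {
    blank <- data[data$conc == 0, ]
    key <- paste(data$phase, round(data$time, 9))
    bkey <- paste(blank$phase, round(blank$time, 9))
    m <- match(key, bkey)
    base <- ifelse(is.na(m), 0, blank$response[m])
    data <- dplyr::mutate(data, response = .data$response - base)
    data <- data[data$conc > 0, ]
  }
  kd0 <- init_kd(data)
  rmax0 <- 1.5 * max(data$response)
  if (!is.finite(rmax0) || rmax0 <= 0) rmax0 <- 1
  theta0 <- log(c(ka = 1e5, kd = kd0, Rmax = rmax0))
  resid_fun <- function(theta) {
    p <- exp(theta)
    pred <- bli_response_at(p[1], p[2], p[3], data, t_assoc)
    data$response - pred
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ptol = 1e-9, ftol = 1e-15))
  p <- exp(fit$par)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("global fit did not converge (", fit$message, ")",
            call. = FALSE)
  }
  KD <- p[["kd"]] / p[["ka"]]
  req <- tibble::tibble(conc = pos,
                        Req = p[["Rmax"]] * pos / (pos + KD))
  structure(list(
    ka = p[["ka"]], kd = p[["kd"]], KD = KD, KD_nM = KD * 1e9,
    Rmax = p[["Rmax"]], rss = sum(resid_fun(fit$par)^2), req = req,
    converged = converged, niter = fit$niter, t_assoc = t_assoc,
    data = data,
    fitted = bli_response_at(p[["ka"]], p[["kd"]], p[["Rmax"]], data, t_assoc)
  ), class = "bli_fit")
}

bli_response_at <- function(ka, kd, Rmax, data, t_assoc) {
  pred <- numeric(nrow(data))
  assoc <- data$phase == "association"
  pred[assoc] <- bli_response(ka, kd, Rmax, data$conc[assoc],
                              data$time[assoc], "association", t_assoc)
  pred[!assoc] <- bli_response(ka, kd, Rmax, data$conc[!assoc],
                               data$time[!assoc], "dissociation", t_assoc)
  pred
}

#' @export
print.bli_fit <- function(x, ...) {
  cat("<bli_fit> 1:1 global fit\n")
  cat(sprintf("  ka = %.3g 1/(M s); kd = %.3g 1/s; KD = %.3g nM; Rmax = %.3g\n",
              x$ka, x$kd, x$KD_nM, x$Rmax))
  cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
              x$rss, nrow(x$data), x$converged))
  invisible(x)
}

#' @method tidy bli_fit
#' @export
tidy.bli_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka", "kd", "KD_nM", "Rmax"),
    estimate = c(x$ka, x$kd, x$KD_nM, x$Rmax),
    unit = c("1/(M s)", "1/s", "nM", "RU")
  )
}

#' @method glance bli_fit
#' @export
glance.bli_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), niter = x$niter,
                 converged = x$converged)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `KD = kd / ka`, reported in nM at 3 significant figures (the precision of
#' published rate-constant tables).
#'
#' @param ka Association rate constant, 1/(M s) (> 0).
#' @param kd Dissociation rate constant, 1/s.
#' @return KD in nM, rounded to 3 significant figures.
#' @export
#' @examples
#' kd_from_rates(7.14e4, 2.22e-2)  # 311 nM
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0)) stop("ka must be positive", call. = FALSE)
  signif(kd / ka * 1e9, 3)
}

#' Published BLI rate constants for XlnR-bound promoter fragments
#'
#' The printed association/dissociation rate constants and equilibrium KD of
#' the MBP-XlnR DNA-binding domain against seven promoter fragments
#' (xylanase and cellulase promoter regions), as published. Used as input
#' for the internal-consistency check `KD = kd/ka`.
#'
#' @return A tibble: `sample_id`, `KD_nM` (printed), `ka`, `kd`.
#' @export
xlnr_bli_rates <- function() {
  path <- system.file("extdata", "xlnr_bli_rates.tsv",
                      package = "gselexmine", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Published regulon-mining summary counts
#'
#' Headline counts of the published XlnR regulon study: number of gSELEX
#' candidate promoters, number of DEGs, size of their intersection, and the
#' 2x2 canonical-motif presence table over the DEGs (intersecting vs
#' non-intersecting).
#'
#' @return A list with `candidates`, `degs`, `intersection` and
#'   `motif_table` (2x2 matrix).
#' @export
xlnr_study_counts <- function() {
  list(
    candidates = 1948L, degs = 72L, intersection = 51L,
    motif_table = matrix(c(44L, 7L, 12L, 9L), nrow = 2, byrow = TRUE,
                         dimnames = list(c("intersection", "other"),
                                         c("motif_present", "motif_absent")))
  )
}
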