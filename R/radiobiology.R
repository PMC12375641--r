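#' Radiobiological model description
#'
#' One row of the outcome-model registry: a dose-response model for a
#' structure/endpoint pair. Two families are supported:
#' \describe{
#'   \item{`poisson_lq`}{phenomenological Poisson response parameterised by
#'     the 50%-response dose `d50` (cGy) and the normalised slope `gamma50`;
#'     doses are converted to EQD2 per DVH bin when `alpha_beta` is given
#'     (the "-LQ" part of the family name).}
#'   \item{`lyman`}{Lyman-Kutcher-Burman probit response parameterised by
#'     `d50` (= TD50(1), whole-volume 50%-complication dose, cGy), slope
#'     factor `m`, and volume-effect parameter `n`; the DVH is reduced to an
#'     EUD with exponent `a = 1/n` unless `a` is given explicitly.}
#' }
#'
#' @param structure structure label the model applies to.
#' @param endpoint free-text clinical endpoint.
#' @param family `"poisson_lq"` or `"lyman"`.
#' @param d50 D50 / TD50(1) in cGy, > 0.
#' @param gamma50 normalised slope at 50% response (poisson_lq only).
#' @param m slope factor (lyman only), > 0.
#' @param n volume-effect parameter (lyman only), > 0.
#' @param a EUD exponent; defaults to `1/n` for lyman models and 1 otherwise.
#' @param alpha_beta alpha/beta ratio in Gy (NA disables the EQD2 mapping).
#' @param eqd2 apply the per-bin EQD2 transform before evaluating the model?
#'   Defaults to `TRUE` for poisson_lq ("-LQ") models, `FALSE` for lyman
#'   models, whose published TD50/m were fitted to physical dose.
#' @return object of class `radbio_model`.
#' @export
radbio_model <- function(structure, endpoint, family = c("poisson_lq", "lyman"),
                         d50, gamma50 = NA_real_, m = NA_real_, n = NA_real_,
                         a = NA_real_, alpha_beta = NA_real_, eqd2 = NULL) {
  family <- match.arg(family)
  if (!is.finite(d50) || d50 <= 0) stop("`d50` must be > 0 (cGy)")
  if (family == "lyman") {
    if (!is.finite(m) || m <= 0) stop("lyman model requires slope factor m > 0")
    if (!is.finite(n) || n <= 0) stop("lyman model requires volume parameter n > 0")
    if (!is.finite(a)) a <- 1 / n
  }
  if (is.null(eqd2)) eqd2 <- (family == "poisson_lq") && is.finite(alpha_beta)
  structure(list(structure = structure, endpoint = endpoint, family = family,
                 d50 = d50, gamma50 = gamma50, m = m, n = n, a = a,
                 alpha_beta = alpha_beta, eqd2 = isTRUE(eqd2)),
            class = "radbio_model")
}

#' @export
print.radbio_model <- function(x, ...) {
  cat(sprintf("<radbio_model> %s / %s [%s]\n", x$structure, x$endpoint, x$family))
  cat(sprintf("  d50 %.0f cGy  gamma50 %s  m %s  n %s  a %s  a/b %s Gy  eqd2 %s\n",
              x$d50, format(x$gamma50), format(x$m), format(x$n),
              format(x$a), format(x$alpha_beta), x$eqd2))
  invisible(x)
}

#' Built-in thoracic model registry
#'
#' The default registry of TCP/NTCP models for thoracic plan evaluation:
#' a Poisson-LQ tumour-control model for the PTV (D50 4920 cGy), two
#' Lyman lung models (pneumonitis within 6 months, TD50 2190 cGy, m 0.80,
#' n 0.37; fibrosis beyond 6 months, TD50 2880 cGy, m 0.5, n 0.34), a
#' Poisson-LQ esophageal stricture model (D50 6800 cGy) and a Lyman
#' esophagitis model (TD50 5100 cGy, m 0.32, n 0.44). The published sources
#' of the Poisson models do not fix a normalised slope, so `gamma50` (default
#' 1.5, a mid-range literature value for lung tumours) is a configuration
#' argument and is stamped on every model.
#'
#' @param gamma50_ptv normalised slope for the PTV control model.
#' @param gamma50_esophagus normalised slope for the stricture model.
#' @return list of [radbio_model()] objects keyed `"structure:endpoint"`.
#' @export
default_models <- function(gamma50_ptv = 1.5, gamma50_esophagus = 1.5) {
  models <- list(
    radbio_model("PTV", "Tumor control", "poisson_lq",
                 d50 = 4920, gamma50 = gamma50_ptv, alpha_beta = 10),
    radbio_model("Lungs", "Symptomatic or radiographic pneumonitis (<=6 months)",
                 "lyman", d50 = 2190, m = 0.80, n = 0.37, alpha_beta = 3),
    radbio_model("Lungs", "Symptomatic or radiographic fibrosis (>6 months)",
                 "lyman", d50 = 2880, m = 0.5, n = 0.34, alpha_beta = 3),
    radbio_model("Esophagus", "Clinical stricture", "poisson_lq",
                 d50 = 6800, gamma50 = gamma50_esophagus, alpha_beta = 3),
    radbio_model("Esophagus", "Esophagitis grade >= 2", "lyman",
                 d50 = 5100, m = 0.32, n = 0.44, alpha_beta = 10)
  )
  names(models) <- vapply(models, function(m)
    paste(m$structure, m$endpoint, sep = ":"), character(1))
  models
}

#' Fractionation scheme
#'
#' @param prescription total prescription dose (cGy), > 0.
#' @param n_fractions number of fractions, positive integer.
#' @return object of class `fractionation` with the per-fraction dose.
#' @export
fractionation <- function(prescription, n_fractions) {
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0 (cGy)")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions <= 0)
    stop("`n_fractions` must be a positive integer")
  structure(list(prescription = prescription, n_fractions = n_fractions,
                 dose_per_fraction = prescription / n_fractions),
            class = "fractionation")
}

#' EQD2 transform of a differential DVH
#'
#' Maps each bin dose D to its equivalent dose in 2 Gy fractions under the
#' linear-quadratic model, `D * (d + ab) / (200 + ab)` with per-bin fraction
#' dose `d = D / n_fractions` and `ab = 100 * alpha_beta` (all in cGy).
#' Volumes are unchanged. The map is the identity when d = 2 Gy exactly and
#' in the limit alpha/beta -> Inf.
#'
#' @param dvh a [differential_dvh()].
#' @param alpha_beta alpha/beta ratio in Gy, > 0 (may be `Inf`).
#' @param scheme a [fractionation()] giving the number of fractions over
#'   which each bin dose is delivered.
#' @return a [differential_dvh()] on the EQD2 dose scale.
#' @export
eqd2_transform <- function(dvh, alpha_beta, scheme) {
  stopifnot(inherits(dvh, "dvh_diff"), inherits(scheme, "fractionation"))
  if (!(alpha_beta > 0)) stop("`alpha_beta` must be > 0 (Gy)")
  if (is.infinite(alpha_beta)) return(dvh)
  ab <- alpha_beta * 100                           # Gy -> cGy
  f <- function(D) D * (D / scheme$n_fractions + ab) / (200 + ab)
  edges <- f(dvh$bin_edges)
  # the LQ map is strictly increasing for D >= 0, so edges stay sorted
  differential_dvh(edges, dvh$bin_volume, structure = dvh$structure,
                   total_volume = dvh$total_volume)
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Equivalent uniform dose (generalised power mean)
#'
#' `EUD = (sum_i v_i D_i^a)^(1/a)` over the differential DVH with relative
#' volumes v_i and bin-centre doses D_i. `a = 1` gives the mean dose; large
#' positive `a` approaches the maximum dose (serial organ), `a` near 0 is not
#' defined here (`a = 0` errors rather than silently taking the geometric
#' mean). Computed in the log domain so a = 1000 is exact to machine
#' precision.
#'
#' @param dvh a [differential_dvh()].
#' @param a EUD exponent, non-zero.
#' @return EUD in cGy.
#' @export
eud <- function(dvh, a) {
  stopifnot(inherits(dvh, "dvh_diff"))
  if (!is.finite(a) || a == 0)
    stop("`a` must be a non-zero finite exponent (a = 0 not supported)")
  v <- dvh_rel_volumes(dvh)
  d <- dvh_bin_centers(dvh)
  keep <- v > 0
  v <- v[keep]; d <- d[keep]
  if (any(d <= 0)) {
    if (a < 0) return(0)                           # a zero-dose subvolume dominates
    v <- v[d > 0]; d <- d[d > 0]
    if (length(d) == 0L) return(0)
  }
  exp(logsumexp(log(v) + a * log(d)) / a)
}

#' Mechanistic Poisson TCP
#'
#' Tumour control probability under Poisson cell-kill statistics for a
#' uniformly irradiated tumour of `n_clonogens` clonogenic cells with
#' single-hit survival `ps(D) = exp(-alpha D)`:
#' `TCP = exp(-N * exp(-alpha D))`.
#'
#' @param dose uniform dose (cGy), >= 0 (vectorised).
#' @param n_clonogens clonogen number N, > 0.
#' @param alpha cell-kill sensitivity per cGy, > 0.
#' @return probability in (0, 1).
#' @export
tcp_mechanistic <- function(dose, n_clonogens, alpha) {
  if (!(n_clonogens > 0)) stop("`n_clonogens` must be > 0")
  if (!(alpha > 0)) stop("`alpha` must be > 0")
  if (any(dose < 0)) stop("`dose` must be >= 0")
  exp(-n_clonogens * exp(-alpha * dose))
}

#' Phenomenological Poisson TCP at uniform dose
#'
#' Two-parameter reformulation of the Poisson model in terms of the 50%
#' control dose D50 and the normalised slope gamma50:
#' `TCP(D) = (1/2)^exp(2 gamma50 (1 - D/D50) / ln 2)`.
#' At D = D50 the exponent is 1, giving exactly 0.5; the normalised slope
#' `D * dTCP/dD` at D50 equals gamma50.
#'
#' @param dose uniform dose (cGy), >= 0 (vectorised).
#' @param d50 50% control dose (cGy), > 0.
#' @param gamma50 normalised slope, > 0.
#' @return probability in (0, 1).
#' @export
tcp_poisson_uniform <- function(dose, d50, gamma50) {
  if (!(d50 > 0)) stop("`d50` must be > 0")
  if (!(gamma50 > 0)) stop("`gamma50` must be > 0")
  if (any(dose < 0)) stop("`dose` must be >= 0")
  exp(log(0.5) * exp(2 * gamma50 * (1 - dose / d50) / log(2)))
}

# shared DVH preparation for the Poisson-LQ DVH forms
poisson_dvh_exponent <- function(dvh, model, scheme) {
  if (model$family != "poisson_lq")
    stop("model family must be 'poisson_lq'")
  if (!is.finite(model$gamma50) || model$gamma50 <= 0)
    stop(sprintf("model '%s:%s' lacks gamma50; set it in the model registry",
                 model$structure, model$endpoint))
  if (model$eqd2) {
    if (!is.finite(model$alpha_beta))
      stop("eqd2 = TRUE requires a finite alpha_beta")
    if (missing(scheme) || is.null(scheme))
      stop("EQD2 correction requires a fractionation scheme")
    dvh <- eqd2_transform(dvh, model$alpha_beta, scheme)
  }
  v <- dvh_rel_volumes(dvh)
  d <- dvh_bin_centers(dvh)
  sum(v * exp(2 * model$gamma50 * (1 - d / model$d50) / log(2)))
}

#' Poisson TCP of a heterogeneous dose distribution
#'
#' Treats each DVH subvolume as an independent tumourlet: the control
#' probability is the volume-weighted product
#' `TCP = prod_i TCP(D_i)^{v_i} = (1/2)^{sum_i v_i exp(2 gamma50 (1 - D_i/D50)/ln 2)}`,
#' accumulated in the log domain. When the model carries an alpha/beta ratio
#' and `eqd2 = TRUE` (the default for "-LQ" models) bin doses are first
#' converted to EQD2.
#'
#' @param dvh a [differential_dvh()] of the target.
#' @param model a `poisson_lq` [radbio_model()].
#' @param scheme a [fractionation()]; required when the EQD2 correction is on.
#' @return probability in (0, 1).
#' @export
tcp_poisson_dvh <- function(dvh, model, scheme = NULL) {
  stopifnot(inherits(dvh, "dvh_diff"), inherits(model, "radbio_model"))
  exp(log(0.5) * poisson_dvh_exponent(dvh, model, scheme))
}

#' Lyman-Kutcher-Burman NTCP
#'
#' Reduces the DVH to an equivalent uniform dose with exponent `a = 1/n`
#' (volume-effect parameter n), then evaluates the probit dose response
#' `NTCP = Phi(t)` with `t = (EUD - TD50(1)) / (m TD50(1))`. `Phi` is the
#' standard normal CDF, computed via `pnorm` (erfc relation), no table
#' lookup. Whole-organ uniform dose at TD50 gives exactly 0.5.
#'
#' @param dvh a [differential_dvh()] of the organ at risk.
#' @param model a `lyman` [radbio_model()].
#' @param scheme optional [fractionation()] used only when the model was
#'   explicitly configured with `eqd2 = TRUE`.
#' @return probability in (0, 1).
#' @export
ntcp_lkb <- function(dvh, model, scheme = NULL) {
  stopifnot(inherits(dvh, "dvh_diff"), inherits(model, "radbio_model"))
  if (model$family != "lyman") stop("model family must be 'lyman'")
  if (!is.finite(model$m) || model$m <= 0) stop("`m` must be > 0")
  if (model$eqd2) {
    if (is.null(scheme)) stop("EQD2 correction requires a fractionation scheme")
    dvh <- eqd2_transform(dvh, model$alpha_beta, scheme)
  }
  e <- eud(dvh, model$a)
  t <- (e - model$d50) / (model$m * model$d50)
  stats::pnorm(t)
}

#' Poisson-LQ NTCP
#'
#' Seriality-free Poisson dose response applied to an organ-at-risk DVH: the
#' same functional form as [tcp_poisson_dvh()], read as a complication
#' probability. The published parameter tables for these endpoints carry no
#' normalised slope, so `gamma50` must be set on the model (the default
#' registry stamps 1.5).
#'
#' @inheritParams tcp_poisson_dvh
#' @return probability in (0, 1).
#' @export
ntcp_poisson_lq <- function(dvh, model, scheme = NULL) {
  stopifnot(inherits(dvh, "dvh_diff"), inherits(model, "radbio_model"))
  if (model$family != "poisson_lq")
    stop("model family must be 'poisson_lq'")
  if (!is.finite(model$gamma50) || model$gamma50 <= 0)
    stop(sprintf(
      "model '%s:%s' has no gamma50: set gamma50 in the registry/config",
      model$structure, model$endpoint))
  exp(log(0.5) * poisson_dvh_exponent(dvh, model, scheme))
}

# dispatch one model on one DVH
evaluate_model <- function(dvh, model, scheme) {
  if (model$family == "lyman") {
    list(probability = ntcp_lkb(dvh, model, scheme),
         eud = eud(dvh, model$a))
  } else {
    e_dvh <- if (model$eqd2) eqd2_transform(dvh, model$alpha_beta, scheme) else dvh
    list(probability = tcp_poisson_dvh(dvh, model, scheme),
         eud = eud(e_dvh, if (is.finite(model$a)) model$a else 1))
  }
}

#' Evaluate all outcome models over a cohort of DVH sets
#'
#' Applies every registry model to every patient x condition DVH set,
#' producing one probability (and its intermediate EUD) per row. A missing
#' structure is recorded as an error message in that row and the run
#' continues.
#'
#' @param cohort_dvhs nested list: `cohort_dvhs[[patient]][[condition]]` is a
#'   named list of [differential_dvh()] objects keyed by structure name.
#' @param models list of [radbio_model()], e.g. [default_models()].
#' @param scheme a [fractionation()].
#' @return `data.frame` (class `outcome_table`) with columns patient,
#'   condition, structure, endpoint, family, eud_cGy, probability, error.
#' @export
evaluate_outcomes <- function(cohort_dvhs, models = default_models(),
                              scheme) {
  stopifnot(inherits(scheme, "fractionation"))
  rows <- list()
  for (pat in names(cohort_dvhs)) {
    for (cond in names(cohort_dvhs[[pat]])) {
      dvhs <- cohort_dvhs[[pat]][[cond]]
      for (model in models) {
        row <- data.frame(patient = pat, condition = cond,
                          structure = model$structure,
                          endpoint = model$endpoint, family = model$family,
                          eud_cGy = NA_real_, probability = NA_real_,
                          error = NA_character_, stringsAsFactors = FALSE)
        dvh <- dvhs[[model$structure]]
        if (is.null(dvh)) {
          row$error <- sprintf("structure '%s' missing", model$structure)
        } else {
          res <- evaluate_model(dvh, model, scheme)
          row$eud_cGy <- res$eud
          row$probability <- res$probability
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_table", "data.frame")
  out
}
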