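#' The packaged stem-cell-zoo species table
#'
#' Per-species segmentation-clock measurements: the six in vitro clock
#' periods and, for the four species measured in the degradation and
#' intron-delay assays, the HES7 protein half-life and intron delay. Mouse
#' and human kinetics come from earlier work and are deliberately left `NA`
#' here; supply them via `extra_kinetics` in [kinetics_scaling_report()] if
#' available. Organismal traits (adult body weight, gestation length,
#' embryogenesis length) are user-supplied inputs with this schema —
#' `species_zoo_table()` ships them as `NA` and any fit simply drops
#' incomplete rows (with the count reported).
#'
#' Columns: `species`, `clade` (Primates/Glires/Ungulates), `period` (min),
#' `hes7_halflife` (min), `intron_delay` (min), `body_weight_g`,
#' `gestation_days`, `embryogenesis_days`, `tbx6_halflife` (min),
#' `median_cell_volume_fl`. Optional fields are explicitly `NA`, never
#' imputed.
#'
#' @return A data frame with one row per species.
#' @export
#' @examples
#' species_zoo_table()
species_zoo_table <- function() {
  data.frame(
    species = c("mouse", "rabbit", "rhinoceros", "cattle", "human", "marmoset"),
    clade = c("Glires", "Glires", "Ungulates", "Ungulates", "Primates", "Primates"),
    period = c(122, 153, 236, 238, 322, 388),
    hes7_halflife = c(NA, 24, 32, 33, NA, 46),
    intron_delay = c(NA, 24, 36, 37, NA, 54),
    body_weight_g = NA_real_,
    gestation_days = NA_real_,
    embryogenesis_days = NA_real_,
    tbx6_halflife = NA_real_,
    median_cell_volume_fl = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Linear scaling fit of clock period against a trait
#'
#' Ordinary least squares of `period` on a (possibly log10-transformed)
#' predictor across species, as used for the trait panels (body weight on
#' log10 scale, gestation and embryogenesis length on identity scale). Rows
#' with a missing response or predictor are dropped and counted — never
#' imputed.
#'
#' @param table A species table (see [species_zoo_table()] for the schema).
#' @param predictor Name of the predictor column.
#' @param transform `"identity"` or `"log10"`.
#' @param response Name of the response column (default `"period"`).
#' @return A list of class `scaling_fit`: `predictor`, `transform`, `slope`,
#'   `intercept`, `r_squared`, `n`, `n_dropped`.
#' @export
#' @examples
#' tab <- species_zoo_table()
#' tab$embryogenesis_days <- c(9, 10, NA, 12, 15, 18)
#' linear_scaling_fit(tab, "embryogenesis_days")
linear_scaling_fit <- function(table, predictor, transform = c("identity", "log10"),
                               response = "period") {
  transform <- match.arg(transform)
  if (!predictor %in% names(table)) {
    stop(sprintf("predictor column '%s' not found", predictor), call. = FALSE)
  }
  x <- table[[predictor]]
  y <- table[[response]]
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 species with both fields present", call. = FALSE)
  }
  if (transform == "log10") {
    if (any(x <= 0)) stop("log10 transform needs positive predictor values", call. = FALSE)
    x <- log10(x)
  }
  if (stats::sd(x) == 0) stop("degenerate design: predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- list(
    predictor = predictor,
    transform = transform,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    # exact linear fixtures trip the "essentially perfect fit" note
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = length(x),
    n_dropped = n_dropped
  )
  class(res) <- "scaling_fit"
  res
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> period ~ %s(%s): slope %.4g, intercept %.4g, R2 %.3f (n = %d, %d dropped)\n",
              x$transform, x$predictor, x$slope, x$intercept, x$r_squared,
              x$n, x$n_dropped))
  invisible(x)
}

#' In vivo somite formation period from embryo staging data
#'
#' Regresses somite count on embryonic day across staged embryos; the slope
#' is the somite formation rate (somites/day) and the period is `1440 /
#' slope` minutes.
#'
#' @param staging Data frame with columns `day` (embryonic day) and
#'   `somites` (somite count), >= 3 records.
#' @return Somite formation period in minutes.
#' @export
#' @examples
#' somite_period(data.frame(day = c(8, 8.5, 9), somites = c(5, 17, 29)))
somite_period <- function(staging) {
  if (!all(c("day", "somites") %in% names(staging))) {
    stop("staging table needs columns `day` and `somites`", call. = FALSE)
  }
  if (nrow(staging) < 3L) stop("need at least 3 staging records", call. = FALSE)
  if (any(staging$somites < 0)) stop("somite counts must be >= 0", call. = FALSE)
  fit <- stats::lm(somites ~ day, data = staging)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid staging: somite count does not increase with embryonic day",
         call. = FALSE)
  }
  1440 / slope
}

#' Fold-difference between the slowest and fastest clocks
#'
#' `max(period) / min(period)` across species, rounded to one decimal for
#' reporting (the headline fold-difference across the zoo).
#'
#' @param table A species table with a `period` column, or a numeric vector
#'   of periods.
#' @return Dimensionless ratio, rounded to 1 decimal.
#' @export
#' @examples
#' period_ratio_extremes(species_zoo_table()) # 3.2
period_ratio_extremes <- function(table) {
  periods <- if (is.numeric(table)) table else table$period
  periods <- periods[is.finite(periods)]
  if (length(periods) < 2L) stop("need at least 2 periods", call. = FALSE)
  round(max(periods) / min(periods), 1)
}

#' Period-versus-kinetics scaling fits
#'
#' Three ordinary linear fits summarizing how the clock period scales with
#' the measured feedback-loop kinetics across species: `period ~
#' hes7_halflife`, `period ~ intron_delay`, and the proportionality of the
#' two kinetic parameters themselves (`hes7_halflife ~ intron_delay`). Rows
#' missing a required field are dropped per fit (and counted).
#'
#' @param table A species table (see [species_zoo_table()]).
#' @param extra_kinetics Optional data frame with columns `species`,
#'   `hes7_halflife`, `intron_delay` used to fill in species whose kinetics
#'   come from external sources (e.g. previously published mouse/human
#'   values).
#' @return A named list of [linear_scaling_fit()] results:
#'   `period_vs_halflife`, `period_vs_delay`, `halflife_vs_delay`.
#' @export
kinetics_scaling_report <- function(table, extra_kinetics = NULL) {
  if (!is.null(extra_kinetics)) {
    i <- match(extra_kinetics$species, table$species)
    if (anyNA(i)) stop("unknown species in `extra_kinetics`", call. = FALSE)
    table$hes7_halflife[i] <- extra_kinetics$hes7_halflife
    table$intron_delay[i] <- extra_kinetics$intron_delay
  }
  n_kin <- sum(is.finite(table$hes7_halflife) & is.finite(table$intron_delay))
  if (n_kin < 4L) {
    stop("need kinetics for at least 4 species", call. = FALSE)
  }
  list(
    period_vs_halflife = linear_scaling_fit(table, "hes7_halflife"),
    period_vs_delay = linear_scaling_fit(table, "intron_delay"),
    halflife_vs_delay = linear_scaling_fit(table, "intron_delay",
                                           response = "hes7_halflife")
  )
}
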