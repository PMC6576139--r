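#' REML fit of the multi-environment trial model
#'
#' Fits the plot-level mixed model
#' \deqn{Y = \mu + G_a + L_b + GL_{ab} + b_i + c_j + r_k + \epsilon}
#' by REML (via lme4), with location fixed and genotype, genotype x
#' location, replication, column-within-replication and
#' row-within-replication random. Genotype is treated as random so that
#' BLUPs of genotype values are defined; replications (and their rows and
#' columns) are nested within location.
#'
#' @param records trial records as produced by [simulate_trial()]: columns
#'   `genotype`, `location`, `rep`, `value`, and optionally `row` and `col`
#'   (the spatial terms are included only when both are present).
#' @return list of class `trial_fit`: `varcomp` (named vector `g`, `gl`,
#'   `rep`, `col`, `row`, `resid`), `blup` (named vector of predicted
#'   genotype values, intercept included), `mu`, `n_locations`, `n_reps`,
#'   `converged`.
#' @export
fit_trial_model <- function(records) {
  need <- c("genotype", "location", "rep", "value")
  stopifnot(all(need %in% names(records)))
  if (length(unique(records$genotype)) < 2L) stop("need >= 2 genotypes")
  df <- records
  df$genotype <- factor(df$genotype)
  df$location <- factor(df$location)
  df$rep_id <- interaction(df$location, df$rep, drop = TRUE)
  has_grid <- all(c("row", "col") %in% names(records))
  if (has_grid) {
    df$col_id <- interaction(df$rep_id, df$col, drop = TRUE)
    df$row_id <- interaction(df$rep_id, df$row, drop = TRUE)
  }
  multi_loc <- nlevels(df$location) > 1L
  terms <- c(if (multi_loc) "location",
             "(1 | genotype)",
             if (multi_loc) "(1 | genotype:location)",
             "(1 | rep_id)",
             if (has_grid) c("(1 | col_id)", "(1 | row_id)"))
  form <- stats::reformulate(terms, response = "value")
  environment(form) <- environment()
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore",
                      calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  varcomp <- c(
    g = get_vc("genotype"),
    gl = if (multi_loc) get_vc("genotype:location") else 0,
    rep = get_vc("rep_id"),
    col = if (has_grid) get_vc("col_id") else 0,
    row = if (has_grid) get_vc("row_id") else 0,
    resid = get_vc("Residual")
  )
  mu <- unname(lme4::fixef(fit)[["(Intercept)"]])
  # predicted genotype value: intercept + mean fixed location effect + BLUP
  fe <- lme4::fixef(fit)
  loc_fe <- fe[grepl("^location", names(fe))]
  base <- mu + sum(loc_fe) / nlevels(df$location)
  re <- lme4::ranef(fit)$genotype
  blup <- stats::setNames(base + re[["(Intercept)"]], rownames(re))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  structure(list(varcomp = varcomp, blup = blup, mu = mu,
                 n_locations = nlevels(df$location),
                 n_reps = max(as.integer(records$rep)),
                 converged = conv),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("trial_fit variance components:\n")
  print(round(x$varcomp, 4))
  cat(sprintf("mu = %.3f, %d genotypes, %d locations\n",
              x$mu, length(x$blup), x$n_locations))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GL}/l +
#'   \sigma^2_\epsilon/(l r))}
#' with `l` locations and `r` replications per location: the fraction of
#' entry-mean phenotypic variance attributable to genotypes.
#'
#' @param fit a [fit_trial_model()] result, or a named vector/list with
#'   elements `g`, `gl`, `resid`.
#' @param n_locations,n_reps realized design dimensions; defaulted from the
#'   fit when available.
#' @return h2 as a fraction in \[0, 1\].
#' @examples
#' heritability(c(g = 1, gl = 0, resid = 1), n_locations = 3, n_reps = 2)
#' @export
heritability <- function(fit, n_locations = NULL, n_reps = NULL) {
  vc <- if (inherits(fit, "trial_fit")) fit$varcomp else unlist(fit)
  if (is.null(n_locations) && inherits(fit, "trial_fit")) {
    n_locations <- fit$n_locations
  }
  if (is.null(n_reps) && inherits(fit, "trial_fit")) n_reps <- fit$n_reps
  stopifnot(!is.null(n_locations), !is.null(n_reps))
  g <- vc[["g"]]
  gl <- if ("gl" %in% names(vc)) vc[["gl"]] else 0
  e <- vc[["resid"]]
  denom <- g + gl / n_locations + e / (n_locations * n_reps)
  if (denom == 0) stop("zero phenotypic variance: h2 undefined")
  unname(g / denom)
}
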