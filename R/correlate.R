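#' Squared Pearson correlation with least-squares line
#'
#' R-squared is the squared Pearson correlation of the paired values, which
#' for an intercept-including ordinary least squares fit coincides with the
#' coefficient of determination; slope and intercept come from the OLS line
#' `y ~ x`.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite).
#' @param labels optional point labels.
#' @return object of class `correlation_fit`: list with `r_squared`,
#'   `slope`, `intercept`, `n_points`, `labels`, `x`, `y`.
#' @export
squared_pearson <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in correlation input")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  fit <- lm(y ~ x)
  structure(list(r_squared = cor(x, y)^2,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_points = length(x),
                 labels = labels, x = x, y = y),
            class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat(sprintf("<correlation_fit> R^2 = %.3f, y = %.4f x + %.4f (n = %d)\n",
              x$r_squared, x$slope, x$intercept, x$n_points))
  invisible(x)
}

# Mapping between mutant/truncation system names and peptide sequences.
# Histidine systems share one peptide per position; the tautomer is a
# modelling choice, not a different sequence.
system_peptide_map <- function() {
  c(WT = "LRRASLG",
    R18A = "LARASLG", R19A = "LRAASLG",
    R18K = "LKRASLG", R19K = "LRKASLG",
    R18Hd = "LHRASLG", R18He = "LHRASLG", R18Hp = "LHRASLG",
    R19Hd = "LRHASLG", R19He = "LRHASLG", R19Hp = "LRHASLG",
    RRASLG = "RRASLG", RASLG = "RASLG", LRRASL = "LRRASL")
}

#' Histidine tautomer codes
#'
#' `"Hd"` (neutral, proton on Nd1), `"He"` (neutral, proton on Ne2) and
#' `"Hp"` (protonated imidazolium, +1).
#' @export
histidine_tautomers <- function() c("Hd", "He", "Hp")

# Pull calculated ddg and experimental ddg_catalysis for a set of system
# names; errors name any missing system/peptide.
paired_points <- function(systems, calc_table, exp_table) {
  calc_table <- as.data.frame(calc_table)
  exp_table <- as.data.frame(exp_table)
  ci <- match(systems, calc_table$system)
  if (anyNA(ci))
    stop("calculated table is missing system(s): ",
         paste(systems[is.na(ci)], collapse = ", "))
  pep <- system_peptide_map()[systems]
  ei <- match(pep, exp_table$peptide)
  if (anyNA(ei))
    stop("experimental table is missing peptide(s): ",
         paste(pep[is.na(ei)], collapse = ", "))
  data.frame(system = systems,
             ddg_calc = calc_table$ddg[ci],
             ddg_exp = exp_table$ddg_catalysis[ei],
             stringsAsFactors = FALSE)
}

#' Assemble the seven-point mutant dataset for one tautomer pair
#'
#' The wild type, the four non-histidine arginine mutants (R18A, R19A,
#' R18K, R19K) and one chosen histidine model per mutated position, paired
#' with the experimental catalysis shifts, in deterministic label order.
#'
#' @param calc_table data frame `(system, ddg)` of calculated binding
#'   shifts; must contain WT, the four non-His mutants and all six
#'   histidine models (`R18Hd`, `R18He`, `R18Hp`, `R19Hd`, `R19He`,
#'   `R19Hp`).
#' @param exp_table a [shifts_table()] result.
#' @param his18_variant,his19_variant tautomer at each position, one of
#'   [histidine_tautomers()].
#' @return data frame `(system, ddg_calc, ddg_exp)`, 7 rows.
#' @export
assemble_mutant_dataset <- function(calc_table, exp_table,
                                    his18_variant, his19_variant) {
  his18_variant <- match.arg(his18_variant, histidine_tautomers())
  his19_variant <- match.arg(his19_variant, histidine_tautomers())
  systems <- c("WT", "R18A", "R19A", "R18K", "R19K",
               paste0("R18", his18_variant), paste0("R19", his19_variant))
  paired_points(systems, calc_table, exp_table)
}

#' Select histidine protonation states by R-squared maximisation
#'
#' Evaluates the calculated-versus-experimental correlation for all nine
#' (tautomer at 18) x (tautomer at 19) assemblies and reports the full grid
#' with the maximising pair(s). Ties are all reported, never silently
#' broken.
#'
#' @inheritParams assemble_mutant_dataset
#' @return object of class `protonation_grid`: list with `grid` (3 x 3
#'   R-squared matrix, rows = position 18, cols = position 19), `fits`
#'   (named list of `correlation_fit`), `best` (data frame of maximising
#'   pair(s)), `best_fit`.
#' @export
select_histidine_pair <- function(calc_table, exp_table) {
  taut <- histidine_tautomers()
  grid <- matrix(NA_real_, 3L, 3L, dimnames = list(taut, taut))
  fits <- list()
  for (a in taut) for (b in taut) {
    pts <- assemble_mutant_dataset(calc_table, exp_table, a, b)
    fit <- squared_pearson(pts$ddg_calc, pts$ddg_exp, labels = pts$system)
    grid[a, b] <- fit$r_squared
    fits[[paste(a, b, sep = "/")]] <- fit
  }
  best_val <- max(grid)
  hit <- which(grid >= best_val - 1e-12, arr.ind = TRUE)
  best <- data.frame(his18 = taut[hit[, 1L]], his19 = taut[hit[, 2L]],
                     r_squared = grid[hit], stringsAsFactors = FALSE)
  structure(list(grid = grid, fits = fits, best = best,
                 best_fit = fits[[paste(best$his18[1L], best$his19[1L],
                                        sep = "/")]]),
            class = "protonation_grid")
}

#' @export
print.protonation_grid <- function(x, ...) {
  cat("<protonation_grid> R^2 by (position 18, position 19):\n")
  print(round(x$grid, 3))
  cat(sprintf("best: %s@18, %s@19 (R^2 = %.3f)%s\n",
              x$best$his18[1L], x$best$his19[1L], x$best$r_squared[1L],
              if (nrow(x$best) > 1L) sprintf(" [tied %d ways]", nrow(x$best))
              else ""))
  invisible(x)
}

#' Full ten-point correlation model
#'
#' The seven mutant-set points for the chosen tautomer pair plus the three
#' shorter-chain peptides (RRASLG, RASLG, LRRASL).
#'
#' @param calc_mutants calculated shifts for the mutant systems (as in
#'   [assemble_mutant_dataset()]).
#' @param calc_short calculated shifts `(system, ddg)` for `RRASLG`,
#'   `RASLG`, `LRRASL`.
#' @param exp_table a [shifts_table()] result.
#' @param his18_variant,his19_variant the chosen tautomer pair.
#' @return a `correlation_fit` over 10 points.
#' @export
full_model <- function(calc_mutants, calc_short, exp_table,
                       his18_variant, his19_variant) {
  m7 <- assemble_mutant_dataset(calc_mutants, exp_table,
                                his18_variant, his19_variant)
  s3 <- paired_points(c("RRASLG", "RASLG", "LRRASL"), calc_short, exp_table)
  pts <- rbind(m7, s3)
  squared_pearson(pts$ddg_calc, pts$ddg_exp, labels = pts$system)
}

#' Predict a catalysis shift from a calculated binding shift
#'
#' Applies the fitted linear predictor `slope * x + intercept`.
#'
#' @param model a `correlation_fit`.
#' @param ddg_es_calc calculated binding shift(s), kcal/mol.
#' @return predicted catalysis shift(s), kcal/mol, with the model's
#'   R-squared attached as attribute `r_squared`.
#' @export
predict_ddg_ts <- function(model, ddg_es_calc) {
  stopifnot(inherits(model, "correlation_fit"))
  structure(model$slope * ddg_es_calc + model$intercept,
            r_squared = model$r_squared)
}
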