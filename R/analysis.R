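# Cross-cutting analysis: K-phi correlation, variant comparisons,
# incomplete-recovery detection, and the end-to-end pipeline.

#' Correlation between equilibrium size and return time
#'
#' Pearson correlation of K and phi for one species across converged
#' perturbed design cells (landscape x intensity), with the two-sided
#' t-distribution p-value. Unperturbed cells never contribute (phi is not
#' defined for them). Zero variance in K or phi yields an undefined marker
#' (`NA`), not a number.
#'
#' @param results results table (see [fit_design()]), with columns
#'   `species`, `intensity`, `K`, `phi`, `converged`.
#' @param species species name to subset on.
#' @return list with elements `r`, `p`, `n`.
#' @export
correlate_K_phi <- function(results, species) {
  d <- results[results$species == species & results$intensity > 0 &
                 results$converged & is.finite(results$K) &
                 is.finite(results$phi), ]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 converged (K, phi) pairs for ", species)
  if (stats::sd(d$K) == 0 || stats::sd(d$phi) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(d$K, d$phi)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Test for incomplete recovery across successive perturbations
#'
#' Weighted linear trend of per-segment asymptotes on segment index
#' (weights 1/SE^2). Recovery is flagged incomplete when the 95% CI of the
#' slope lies entirely below zero.
#'
#' @param segment_Ks data.frame from [segmentwise_K()] (columns `segment`,
#'   `K`, `se_K`).
#' @return list with `slope`, `ci` (length 2), `incomplete_recovery`.
#' @export
recovery_decline_test <- function(segment_Ks) {
  if (nrow(segment_Ks) < 3L) stop("need at least 3 segments")
  w <- 1 / pmax(segment_Ks$se_K, 1e-12)^2
  fit <- stats::lm(K ~ segment, data = segment_Ks, weights = w)
  ci <- stats::confint(fit)["segment", ]
  list(slope = unname(stats::coef(fit)["segment"]),
       ci = unname(ci),
       incomplete_recovery = unname(ci[2L] < 0))
}

#' Differences in K and phi between consecutive landscape variants
#'
#' Per species and intensity, signed differences for the transitions A->B,
#' B->C, C->D where both fits exist (a missing variant's rows are omitted
#' with a notice attribute). Approximate 95% CIs are propagated from the
#' fits' bootstrap intervals (half-width / 1.96 as SE, combined in
#' quadrature).
#'
#' @param results results table (see [fit_design()]).
#' @return data.frame (species, intensity, transition, dK, dK_lo, dK_hi,
#'   dphi, dphi_lo, dphi_hi).
#' @export
compare_variants <- function(results) {
  d <- results[results$converged & is.finite(results$K), ]
  trans <- list(c("A", "B"), c("B", "C"), c("C", "D"))
  rows <- list()
  notes <- character(0)
  for (sp in unique(d$species)) for (iv in unique(d$intensity[d$species == sp])) {
    sub <- d[d$species == sp & d$intensity == iv, ]
    for (tr in trans) {
      a <- sub[sub$variant == tr[1L], ]
      b <- sub[sub$variant == tr[2L], ]
      if (nrow(a) != 1L || nrow(b) != 1L) {
        notes <- c(notes, paste0(sp, "/", iv, ": transition ",
                                 tr[1L], "->", tr[2L], " missing a fit"))
        next
      }
      se <- function(lo, hi) if (is.finite(lo) && is.finite(hi)) (hi - lo) / 3.92 else NA_real_
      dK <- b$K - a$K
      sK <- sqrt(se(a$K_lo, a$K_hi)^2 + se(b$K_lo, b$K_hi)^2)
      dphi <- b$phi - a$phi
      sphi <- sqrt(se(a$phi_lo, a$phi_hi)^2 + se(b$phi_lo, b$phi_hi)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, intensity = iv,
        transition = paste0(tr[1L], "->", tr[2L]),
        dK = dK, dK_lo = dK - 1.96 * sK, dK_hi = dK + 1.96 * sK,
        dphi = dphi, dphi_lo = dphi - 1.96 * sphi,
        dphi_hi = dphi + 1.96 * sphi, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), intensity = numeric(0),
               transition = character(0), dK = numeric(0))
  attr(out, "notes") <- notes
  out
}

# Runs-test form selection: fit form 3 and look for structured early-time
# residuals (one-sided runs test on residual signs at t <= m); a
# significantly low number of runs indicates the S-shape on the log scale
# needs the lower asymptote.
select_form <- function(segments, alpha = 0.05) {
  f3 <- tryCatch(fit_recovery(segments, form = 3, n_boot = 0),
                 error = function(e) NULL)
  if (is.null(f3) || !f3$converged) return(3L)
  early <- f3$data$t <= f3$m
  r <- f3$residuals[early]
  if (length(r) < 8L) return(3L)
  s <- sign(r)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L) return(4L)
  runs <- 1L + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / (n1 + n2)
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  p <- stats::pnorm((runs - mu) / sqrt(max(v, 1e-12)))
  if (p < alpha) 4L else 3L
}

#' Fit every run of a design
#'
#' Perturbed cells are segmented and fitted with [fit_recovery()] (the
#' skylark archetype uses the 4-parameter form; `form = "auto"` applies a
#' one-sided runs test on early-time residuals); unperturbed cells get the
#' intercept-only equilibrium fit (K only, no phi).
#'
#' @param runs output of [run_design()].
#' @param form "default" (4-parameter for skylark, 3 otherwise), "auto", 3
#'   or 4.
#' @param n_boot bootstrap replicates per fit.
#' @param seed integer seed for the bootstrap streams.
#' @return list with `results` (one row per cell: species, intensity,
#'   variant, K, K_lo, K_hi, phi, phi_lo, phi_hi, form, converged, error)
#'   and `fits` (the fit objects).
#' @export
fit_design <- function(runs, form = "default", n_boot = 200L, seed = 1L) {
  rows <- vector("list", length(runs))
  fits <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    cell <- runs[[i]]$descriptor
    row <- data.frame(species = cell$species, intensity = cell$intensity,
                      variant = cell$variant, K = NA_real_, K_lo = NA_real_,
                      K_hi = NA_real_, phi = NA_real_, phi_lo = NA_real_,
                      phi_hi = NA_real_, form = NA_integer_,
                      converged = FALSE, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (!is.null(runs[[i]]$error)) stop(runs[[i]]$error)
      tr <- runs[[i]]$trajectory
      if (cell$intensity == 0) {
        f <- fit_unperturbed(tr)
        row$K <- f$K
        row$form <- 0L
        row$converged <- TRUE
      } else {
        seg <- segment_trajectory(tr)
        fm <- if (identical(form, "default")) {
          if (cell$species == "skylark") 4L else 3L
        } else if (identical(form, "auto")) select_form(seg) else as.integer(form)
        f <- fit_recovery(seg, form = fm, n_boot = n_boot,
                          seed = derive_seed(seed, paste0("boot", i)))
        row$form <- fm
        row$converged <- f$converged
        if (f$converged) {
          row$K <- f$K; row$phi <- f$phi
          if (!is.null(f$ci)) {
            row$K_lo <- f$ci["K", 1L]; row$K_hi <- f$ci["K", 2L]
            row$phi_lo <- f$ci["phi", 1L]; row$phi_hi <- f$ci["phi", 2L]
          }
        } else row$error <- f$diagnostic
      }
      f
    }, error = function(e) {
      row$error <<- conditionMessage(e)
      NULL
    })
    rows[[i]] <- row
    fits[[i]] <- res
  }
  list(results = do.call(rbind, rows), fits = fits)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 120 x 120 mosaic of 250 patches with a road grid,
#' river, buildings and a lake; the beetle and vole archetypes at
#' intensities 0 and 0.95 across all four variants; the full 181-year
#' schedule. Every stage's seed is derived from `seed`.
#'
#' @param extent_cells,n_patches landscape scale.
#' @param species,intensities,variants design factors.
#' @param total_years,burn_in_years,perturbation_interval schedule.
#' @param initial_density initial individuals per habitable cell.
#' @param n_boot bootstrap replicates per fit.
#' @param form form policy passed to [fit_design()].
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts.
#' @return named list of settings.
#' @export
pipeline_config <- function(extent_cells = 120L, n_patches = 250L,
                            species = c("beetle", "vole"),
                            intensities = c(0, 0.95),
                            variants = c("A", "B", "C", "D"),
                            total_years = 181L, burn_in_years = 11L,
                            perturbation_interval = 17L,
                            initial_density = 0.2, n_boot = 100L,
                            form = "default", seed = 1L, out_dir = NULL) {
  as.list(environment())
}

#' Run the full analysis pipeline
#'
#' generate -> variants -> simulate design -> fit -> analyze. Produces a
#' results table mirroring the K / phi per species x variant x intensity
#' structure, per-species K-phi correlations, and consecutive-variant
#' comparisons. When `out_dir` is set, trajectories (TSV), the results
#' table (TSV) and a JSON manifest are written there.
#'
#' @param config list from [pipeline_config()].
#' @return list with `results`, `fits`, `correlations`, `comparisons`,
#'   `landscapes`, `runs`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  barriers <- make_barrier_layout(config$extent_cells,
                                  road_spacing = max(20L, config$extent_cells %/% 3L),
                                  river = TRUE, n_buildings = 8L, n_lakes = 1L,
                                  seed = derive_seed(seed, "barriers"))
  A <- generate_landscape(config$extent_cells, config$n_patches,
                          barrier_layout = barriers,
                          seed = derive_seed(seed, "landscape"))
  variants <- make_variants(A, seed = derive_seed(seed, "variants"))
  design <- experiment_design(species = config$species,
                              intensities = config$intensities,
                              variants = config$variants,
                              master_seed = derive_seed(seed, "design"))
  runs <- run_design(design, variants, total_years = config$total_years,
                     burn_in_years = config$burn_in_years,
                     perturbation_interval = config$perturbation_interval,
                     initial_density = config$initial_density)
  fitres <- fit_design(runs, form = config$form, n_boot = config$n_boot,
                       seed = derive_seed(seed, "boot"))
  correlations <- lapply(stats::setNames(nm = unique(config$species)), function(sp)
    tryCatch(correlate_K_phi(fitres$results, sp), error = function(e)
      list(r = NA_real_, p = NA_real_, n = 0L, error = conditionMessage(e))))
  comparisons <- compare_variants(fitres$results)
  out <- list(results = fitres$results, fits = fitres$fits,
              correlations = correlations, comparisons = comparisons,
              landscapes = variants, runs = runs, config = config)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:", nrow(x$results), "design cells\n")
  print(x$results[, c("species", "intensity", "variant", "K", "phi", "converged")],
        digits = 4)
  for (sp in names(x$correlations)) {
    co <- x$correlations[[sp]]
    if (is.finite(co$r))
      cat(sprintf("K-phi correlation (%s): r = %.2f, p = %.3g, n = %d\n",
                  sp, co$r, co$p, co$n))
  }
  invisible(x)
}

# Write pipeline artifacts: per-run trajectory TSVs, results TSV, manifest.
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj_files <- character(0)
  for (i in seq_along(x$runs)) {
    tr <- x$runs[[i]]$trajectory
    if (is.null(tr)) next
    cell <- x$runs[[i]]$descriptor
    f <- file.path(out_dir, sprintf("trajectory_%s_%s_%g.tsv",
                                    cell$species, cell$variant, cell$intensity))
    utils::write.table(tr, f, sep = "\t", row.names = FALSE, quote = FALSE)
    traj_files <- c(traj_files, basename(f))
  }
  utils::write.table(x$results, file.path(out_dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(seed = x$config$seed,
                   extent_cells = x$config$extent_cells,
                   n_patches = x$config$n_patches,
                   design_cells = nrow(x$results),
                   trajectories = traj_files,
                   correlations = x$correlations)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
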