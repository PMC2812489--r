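# Perturbation-recovery protocol: schedule, population removal, trajectory
# recording, segmenting, and factorial orchestration.

#' Construct a perturbation schedule
#'
#' Defaults are the study conditions: a 181-year run whose first 11 years
#' are burn-in, with a fraction of the population removed every 17th year so
#' the analyzed window (years 12..181, 170 records) holds exactly 10
#' complete 17-year recovery segments. Removal is applied immediately after
#' the 1-January census of years `burn_in + 17 * (k - 1)`, k = 1..10, so the
#' first post-perturbation census (t = 1) falls on year `burn_in + 1`.
#'
#' @param total_years total simulated years.
#' @param burn_in_years initial years excluded from analysis.
#' @param perturbation_interval years between removals.
#' @param removal_fraction fraction of individuals removed (0 disables
#'   perturbation; the study intensities are 0, 0.80 and 0.95).
#' @return object of class `schedule`.
#' @export
make_schedule <- function(total_years = 181L, burn_in_years = 11L,
                          perturbation_interval = 17L,
                          removal_fraction = 0.95) {
  stopifnot(total_years > burn_in_years, perturbation_interval >= 1L,
            removal_fraction >= 0, removal_fraction <= 1)
  if (removal_fraction > 0 &&
      (total_years - burn_in_years) %% perturbation_interval != 0L)
    stop("analyzed window (total - burn-in) must be divisible by the ",
         "perturbation interval")
  structure(list(total_years = as.integer(total_years),
                 burn_in_years = as.integer(burn_in_years),
                 perturbation_interval = as.integer(perturbation_interval),
                 removal_fraction = removal_fraction),
            class = "schedule")
}

# Years whose census is followed by a removal event.
perturbation_years <- function(schedule) {
  if (schedule$removal_fraction == 0) return(integer(0))
  k <- (schedule$total_years - schedule$burn_in_years) %/%
    schedule$perturbation_interval
  schedule$burn_in_years + schedule$perturbation_interval * (seq_len(k) - 1L)
}

#' Remove a fraction of the population at random
#'
#' Exactly `round((1 - fraction) * N)` individuals are retained, chosen
#' uniformly without replacement (spatially unbiased). The exact-count rule
#' keeps removal intensity from being a noise source of its own.
#'
#' @param population a `population` object.
#' @param fraction fraction removed, in [0, 1].
#' @param seed optional integer seed.
#' @return a `population` object.
#' @export
perturb <- function(population, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(population$row)
  if (n == 0L || fraction == 0) return(population)
  keep_n <- round((1 - fraction) * n)
  keep <- local_seed(seed, sample.int(n, keep_n))
  new_population(population$row[keep], population$col[keep])
}

#' Run one perturbation-recovery experiment
#'
#' Simulates `total_years` annual cycles on one landscape. Each year: census
#' at the year start; on perturbation years the removal is applied
#' immediately after the census (so the recorded N is pre-removal); then one
#' annual cycle (breed, disperse, overwinter). Extinction is a valid state:
#' the trajectory completes with zeros and is flagged.
#'
#' @param landscape a `landscape` object.
#' @param species a `species_params` object.
#' @param schedule a `schedule` object.
#' @param seed integer master seed (split into init / weather / run streams).
#' @param initial_density initial individuals per habitable cell.
#' @param weather optional `weather_sequence`; by default one is drawn from
#'   the seed's weather stream.
#' @return a `trajectory`: data.frame (year, N, weather, perturbed,
#'   analyzed, segment, t) with attributes `schedule`, `species`,
#'   `weather_sequence`, `extinct`.
#' @export
run_experiment <- function(landscape, species, schedule, seed = NULL,
                           initial_density = 0.2, weather = NULL) {
  stopifnot(inherits(schedule, "schedule"))
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  if (is.null(weather)) weather <- weather_sequence(seed = derive_seed(seed, "weather"))
  ctx <- species_context(landscape, species)
  pop <- init_population(landscape, species, initial_density,
                         seed = derive_seed(seed, "init"), ctx = ctx)
  tot <- schedule$total_years
  pert_years <- perturbation_years(schedule)
  N <- integer(tot)
  wlab <- weather_label(seq_len(tot), length(weather))
  local_seed(derive_seed(seed, "run"), {
    for (y in seq_len(tot)) {
      N[y] <- census(pop)
      if (y %in% pert_years)
        pop <- perturb(pop, schedule$removal_fraction)
      pop <- step_year(pop, landscape, species, w_y = weather[wlab[y]],
                       ctx = ctx)
    }
  })
  years <- seq_len(tot)
  analyzed <- years > schedule$burn_in_years
  seg <- t_since <- rep(NA_integer_, tot)
  if (length(pert_years)) {
    iv <- schedule$perturbation_interval
    off <- years - schedule$burn_in_years
    seg[analyzed] <- (off[analyzed] - 1L) %/% iv + 1L
    t_since[analyzed] <- (off[analyzed] - 1L) %% iv + 1L
  }
  out <- data.frame(year = years, N = N, weather = wlab,
                    perturbed = years %in% pert_years, analyzed = analyzed,
                    segment = seg, t = t_since)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "schedule") <- schedule
  attr(out, "species") <- species$name
  attr(out, "weather_sequence") <- weather
  attr(out, "extinct") <- any(N[analyzed] == 0L)
  attr(out, "seed") <- seed
  out
}

#' Split a perturbed trajectory into recovery segments
#'
#' One segment per perturbation, t = 1..interval (time since perturbation).
#' Zero-count years keep their record with `lnN = NA` (excluded from
#' fitting, but counted in the `n_zero` attribute, never silently dropped).
#'
#' @param trajectory a perturbed `trajectory`.
#' @return data.frame (segment, t, N, lnN, y) of analyzed records, with
#'   attribute `n_zero`.
#' @export
segment_trajectory <- function(trajectory) {
  sched <- attr(trajectory, "schedule")
  if (is.null(sched) || sched$removal_fraction == 0)
    stop("trajectory is unperturbed; use fit_unperturbed() for its equilibrium")
  d <- trajectory[trajectory$analyzed, ]
  out <- data.frame(segment = d$segment, t = d$t, N = d$N,
                    lnN = ifelse(d$N > 0, log(d$N), NA_real_),
                    y = d$weather)
  attr(out, "n_zero") <- sum(d$N == 0L)
  attr(out, "segment_length") <- sched$perturbation_interval
  out
}

#' Enumerate a factorial experiment design
#'
#' @param species character vector of archetype names.
#' @param intensities removal fractions (0 = unperturbed).
#' @param variants landscape variant labels among "A".."D".
#' @param master_seed integer seed from which distinct per-cell sub-seeds
#'   are drawn.
#' @return object of class `experiment_design` (data.frame of cells plus
#'   attributes).
#' @export
experiment_design <- function(species = c("beetle", "vole", "skylark", "spider"),
                              intensities = c(0, 0.80, 0.95),
                              variants = c("A", "B", "C", "D"),
                              master_seed = 1L) {
  cells <- expand.grid(species = species, intensity = intensities,
                       variant = variants, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells$seed <- local_seed(master_seed,
                           sample.int(2^31 - 2, nrow(cells)))
  structure(cells, class = c("experiment_design", "data.frame"),
            master_seed = master_seed)
}

#' Run a full factorial design
#'
#' One run per design cell (species x intensity x landscape variant), each
#' with its own sub-seed. A failing cell is reported and recorded; other
#' cells are unaffected.
#'
#' @param design an `experiment_design`.
#' @param landscapes named list of `landscape` objects covering the
#'   design's variants (e.g. from [make_variants()]).
#' @param total_years,burn_in_years,perturbation_interval schedule settings
#'   shared across cells.
#' @param initial_density initial individuals per habitable cell.
#' @param weather optional shared `weather_sequence`; by default one is
#'   drawn from the design's master seed so weather years are comparable
#'   across cells.
#' @return list of per-cell results, each
#'   `list(descriptor, trajectory | error)`.
#' @export
run_design <- function(design, landscapes, total_years = 181L,
                       burn_in_years = 11L, perturbation_interval = 17L,
                       initial_density = 0.2, weather = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  miss <- setdiff(unique(design$variant), names(landscapes))
  if (length(miss)) stop("landscapes missing for variant(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(weather))
    weather <- weather_sequence(seed = derive_seed(attr(design, "master_seed"),
                                                   "weather"))
  lapply(seq_len(nrow(design)), function(i) {
    cell <- design[i, ]
    res <- tryCatch({
      sched <- make_schedule(total_years, burn_in_years,
                             perturbation_interval, cell$intensity)
      run_experiment(landscapes[[cell$variant]], make_archetype(cell$species),
                     sched, seed = cell$seed,
                     initial_density = initial_density, weather = weather)
    }, error = function(e) e)
    list(descriptor = cell, trajectory = if (!inherits(res, "error")) res,
         error = if (inherits(res, "error")) conditionMessage(res))
  })
}
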