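#' Population specification for the forward simulator
#'
#' @param name population label.
#' @param diploid_size number of diploid individuals (>= 2).
#' @param latitude degrees, in [-90, 90].
#' @param mean_annual_temp degrees Celsius.
#' @param split_parent label of the population this one splits from, or `NA`
#'   for the root population.
#' @param split_generation generation index at which the split happens.
#' @param s_factor per-population multiplier on the configured selection
#'   coefficient (1 = full selection, 0 = neutral in this population);
#'   lets selection pressure differ between environments.
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, diploid_size, latitude = 0,
                            mean_annual_temp = 10, split_parent = NA,
                            split_generation = 0L, s_factor = 1) {
  if (diploid_size < 2) stop("diploid_size must be >= 2")
  if (latitude < -90 || latitude > 90) stop("latitude must be in [-90, 90]")
  structure(list(name = name, diploid_size = as.integer(diploid_size),
                 latitude = latitude, mean_annual_temp = mean_annual_temp,
                 split_parent = split_parent,
                 split_generation = as.integer(split_generation),
                 s_factor = s_factor),
            class = "population_spec")
}

#' Simulation configuration for the forward simulator
#'
#' @param n_sites number of segregating sites simulated.
#' @param focal_site_index 1-based index of the focal (selected) site.
#' @param s additive per-generation selection coefficient of the derived
#'   allele at the focal site (genotype fitnesses 1, 1+s, 1+2s).
#' @param recombination_rate per-base, per-generation crossover probability.
#' @param generations number of forward generations.
#' @param seed integer RNG seed.
#' @param region_bp physical length of the simulated region (bp).
#' @param n_founders number of distinct founder haplotypes the initial panel
#'   is drawn from; small values emulate a bottlenecked founder pool and give
#'   the panel realistic long-range haplotype sharing.
#' @param init_focal_freq initial derived-allele frequency at the focal site;
#'   `NULL` draws it from `init_freq_range`.
#' @param focal_founders number of founder haplotypes carrying the derived
#'   focal allele; `NULL` (default) uses `round(n_founders * init freq)`.
#'   `focal_founders = 1` gives the derived allele a single-haplotype origin,
#'   the genealogy a hard selective sweep starts from.
#' @param init_freq_range range initial per-site frequencies are drawn from.
#' @param cM_per_Mb genetic-map density used for the panel's cM coordinates
#'   (uniform map).
#' @param selection_start generation at which selection switches on (0 =
#'   selected from the start); generations before it are neutral burn-in.
#' @param introduce_focal when TRUE, the focal site is monomorphic ancestral
#'   through the burn-in and a single derived copy is introduced on one
#'   random haplotype at `selection_start`; the post-introduction phase is
#'   re-run (bounded by `max_establish_retries`, from the same checkpoint)
#'   until the derived allele is still segregating with MAF >=
#'   `establish_maf` at sampling. This is the standard conditioning on an
#'   established, ongoing hard sweep. Single-population runs only.
#' @param establish_maf minimum focal MAF that counts as established.
#' @param establish_range optional frequency interval `c(lo, hi)`; when set,
#'   establishment additionally requires the final derived frequency to fall
#'   inside it (e.g. `c(0.1, 0.5)` samples a sweep mid-rise).
#' @param max_establish_retries retry bound for the establishment loop.
#' @param migration_rate island-model migration: per generation, each
#'   haplotype of a population is replaced with one drawn from the other
#'   populations with this probability (0 = no migration).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites, focal_site_index = ceiling(n_sites / 2),
                       s = 0, recombination_rate = 1e-8, generations = 100L,
                       seed = 1L, region_bp = n_sites * 1000,
                       n_founders = 40L, init_focal_freq = NULL,
                       focal_founders = NULL,
                       init_freq_range = c(0.1, 0.9), cM_per_Mb = 1,
                       selection_start = 0L, introduce_focal = FALSE,
                       establish_maf = 0.05, establish_range = NULL,
                       max_establish_retries = 300L,
                       migration_rate = 0) {
  if (recombination_rate < 0) stop("recombination_rate must be >= 0")
  if (focal_site_index < 1 || focal_site_index > n_sites)
    stop("focal_site_index out of range")
  structure(list(n_sites = as.integer(n_sites),
                 focal_site_index = as.integer(focal_site_index), s = s,
                 recombination_rate = recombination_rate,
                 generations = as.integer(generations), seed = as.integer(seed),
                 region_bp = region_bp, n_founders = as.integer(n_founders),
                 init_focal_freq = init_focal_freq,
                 focal_founders = focal_founders,
                 init_freq_range = init_freq_range, cM_per_Mb = cM_per_Mb,
                 selection_start = as.integer(selection_start),
                 introduce_focal = introduce_focal,
                 establish_maf = establish_maf,
                 establish_range = establish_range,
                 max_establish_retries = as.integer(max_establish_retries),
                 migration_rate = migration_rate),
            class = "sim_config")
}

# one generation of Wright-Fisher reproduction with recombination and
# (optional) additive selection at the focal site; haps is 2N x S
.wf_generation <- function(haps, r_interval, focal, s) {
  .wf_generation_cpp(haps, r_interval, focal, s)
}

#' Forward Wright-Fisher simulation of phased haplotype panels
#'
#' Simulates one or more populations forward in discrete generations with
#' recombination, drift, and additive selection on the derived allele at a
#' focal site. The initial panel is drawn from a finite founder-haplotype
#' pool, so haplotype sharing (and hence EHH structure) resembles a
#' bottlenecked population rather than linkage equilibrium. Daughter
#' populations are seeded from their parent at the specified split
#' generation and evolve independently (no migration).
#'
#' @param populations list of [population_spec()]; the first entry with
#'   `split_parent = NA` is the root.
#' @param config a [sim_config()].
#' @return a list with `panels` (named list of [haplotype_panel()]),
#'   `freq_table` (a [site_frequency_table()]), `focal_site` (index),
#'   `focal_lost` (TRUE when the derived focal allele was lost in every
#'   population), and per-population focal frequencies `focal_freq`.
#' @export
simulate_haplotype_panel <- function(populations, config) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (!length(populations)) stop("at least one population required")
  set.seed(config$seed)
  S <- config$n_sites
  pos_bp <- sort(sample.int(config$region_bp, S))
  r_interval <- pmin(0.5, config$recombination_rate * diff(pos_bp))

  # founder pool
  K <- config$n_founders
  p0 <- stats::runif(S, config$init_freq_range[1], config$init_freq_range[2])
  founders <- matrix(stats::rbinom(K * S, 1L, rep(p0, each = K)), nrow = K)
  focal <- config$focal_site_index
  f0 <- if (is.null(config$init_focal_freq))
    stats::runif(1, config$init_freq_range[1], config$init_freq_range[2]) else config$init_focal_freq
  k_der <- if (is.null(config$focal_founders))
    min(K - 1L, max(1L, round(K * f0))) else
    min(K - 1L, max(1L, as.integer(config$focal_founders)))
  founders[, focal] <- 0L
  founders[seq_len(k_der), focal] <- 1L

  names(populations) <- vapply(populations, `[[`, "", "name")
  roots <- vapply(populations, function(p) is.na(p$split_parent) || !nzchar(as.character(p$split_parent)), TRUE)
  if (!any(roots)) stop("no root population (split_parent = NA)")

  init_panel <- function(n) {
    # stratified founder draw: the focal frequency starts at exactly
    # round(2N * f0) derived copies, so only drift moves it afterwards
    n2 <- 2L * n
    n_der <- round(n2 * f0)
    idx <- c(sample(seq_len(k_der), n_der, replace = TRUE),
             sample(seq(k_der + 1L, K), n2 - n_der, replace = TRUE))
    founders[sample(idx), , drop = FALSE]
  }

  if (config$introduce_focal && length(populations) > 1)
    stop("introduce_focal supports a single population only")

  active <- list()
  for (nm in names(populations)[roots])
    active[[nm]] <- init_panel(populations[[nm]]$diploid_size)
  if (config$introduce_focal)
    for (nm in names(active)) active[[nm]][, focal] <- 0L

  pending <- populations[!roots]
  t_sel <- min(config$selection_start, config$generations)
  step_all <- function(active, pending, gens, s_now) {
    for (gen in gens) {
      due <- names(pending)[vapply(pending, function(p) p$split_generation == gen - 1L, TRUE)]
      for (nm in due) {
        par <- as.character(pending[[nm]]$split_parent)
        if (is.null(active[[par]])) stop("split_parent '", par, "' not active at split time")
        n2 <- 2L * pending[[nm]]$diploid_size
        active[[nm]] <- active[[par]][sample.int(nrow(active[[par]]), n2, replace = TRUE), , drop = FALSE]
      }
      pending <- pending[setdiff(names(pending), due)]
      for (nm in names(active))
        active[[nm]] <- .wf_generation(active[[nm]], r_interval, focal,
                                       s_now * populations[[nm]]$s_factor)
      m <- config$migration_rate
      if (m > 0 && length(active) > 1) {
        pool <- do.call(rbind, active)
        offset <- c(0, cumsum(vapply(active, nrow, 0L)))
        for (i in seq_along(active)) {
          n2i <- nrow(active[[i]])
          k <- stats::rbinom(1L, n2i, m)
          if (k > 0) {
            own <- seq(offset[i] + 1L, offset[i + 1L])
            src <- sample(setdiff(seq_len(nrow(pool)), own), k, replace = TRUE)
            active[[i]][sample.int(n2i, k), ] <- pool[src, , drop = FALSE]
          }
        }
      }
    }
    list(active = active, pending = pending)
  }
  st <- step_all(active, pending, seq_len(t_sel), 0)
  establishment_retries <- 0L
  if (config$introduce_focal && t_sel < config$generations) {
    checkpoint <- st$active[[1]]
    repeat {
      panel2 <- checkpoint
      panel2[sample.int(nrow(panel2), 1L), focal] <- 1L
      st2 <- step_all(stats::setNames(list(panel2), names(st$active)),
                      st$pending, seq(t_sel + 1L, config$generations), config$s)
      fq <- mean(st2$active[[1]][, focal])
      ok <- min(fq, 1 - fq) >= config$establish_maf
      if (ok && !is.null(config$establish_range))
        ok <- fq >= config$establish_range[1] && fq <= config$establish_range[2]
      if (ok) break
      establishment_retries <- establishment_retries + 1L
      if (establishment_retries >= config$max_establish_retries)
        stop("focal allele failed to establish within ",
             config$max_establish_retries, " retries")
    }
    st <- st2
  } else if (t_sel < config$generations) {
    st <- step_all(st$active, st$pending, seq(t_sel + 1L, config$generations),
                   config$s)
  }
  active <- st$active
  pending <- st$pending
  if (length(pending)) stop("split_generation beyond the simulated horizon for: ",
                            paste(names(pending), collapse = ", "))

  panels <- lapply(names(active), function(nm)
    haplotype_panel(active[[nm]], pos_bp, cM_per_Mb = config$cM_per_Mb,
                    population = nm))
  names(panels) <- names(active)
  focal_freq <- vapply(panels, function(p) mean(p$haps[, focal]), 0)
  list(panels = panels, freq_table = site_frequency_table(panels),
       focal_site = focal, focal_lost = all(focal_freq == 0),
       focal_freq = focal_freq, establishment_retries = establishment_retries)
}
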