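#' PAR at depth under exponential (Beer-Lambert) light decay
#'
#' Photosynthetically active radiation at depth `z` given the surface value
#' and a diffuse attenuation coefficient `k`:
#' \eqn{PAR(z) = PAR_0 e^{-kz}}. The conventional photic-zone floor is the
#' depth where PAR falls to 1% of the surface value, \eqn{z = \ln(100)/k}.
#'
#' @param par_surface Surface PAR (µmol photons m^-2 s^-1), positive.
#' @param attenuation_k Attenuation coefficient (1/m), positive.
#' @param depth Depth (m), non-negative. Vectorised.
#' @return PAR at depth, same units as `par_surface`.
#' @export
#' @examples
#' par_at_depth(1000, 0.046, log(100) / 0.046)  # the 1% boundary: 10
par_at_depth <- function(par_surface, attenuation_k, depth) {
  if (any(!is.finite(par_surface)) || any(!is.finite(attenuation_k)) ||
      any(!is.finite(depth))) {
    stop_validation("par_at_depth inputs must be finite")
  }
  if (any(attenuation_k <= 0)) stop_validation("attenuation_k must be positive")
  if (any(depth < 0)) stop_validation("depth must be non-negative")
  par_surface * exp(-attenuation_k * depth)
}

#' The reference 24-dataset sampling design
#'
#' One row per simulated dataset: three reference water columns sampled at
#' four depths each, one oxygen-minimum-zone (OMZ) column at four depths,
#' and eight single-depth sites — 24 datasets at 12 sites, 12 photic and 12
#' aphotic by the 1%-of-surface-PAR rule. Site names follow the study
#' system the generator emulates (open-ocean reference columns, an
#' upwelling OMZ column, surface-water and deep single-depth sites).
#'
#' Columns: `dataset_id`, `site`, `role` (reference/omz/single), `depth_m`,
#' `par_surface`, `attenuation_k`, `do_umol_kg`, `lambda` (mixed-layer
#' weight on the photic community; `NA` means pure: 1 if photic by PAR,
#' else 0) and `effect_scale` (deterministic per-dataset modifier of the
#' marker log fold change, emulating site-to-site differences in enrichment
#' strength).
#'
#' @return A 24-row tibble.
#' @export
reference_design <- function() {
  ref <- function(site, par0, k, depths, o2, scl) {
    tibble(site = site, role = "reference", depth_m = depths,
           par_surface = par0, attenuation_k = k, do_umol_kg = o2,
           lambda = NA_real_, effect_scale = scl)
  }
  design <- bind_rows(
    ref("ATII",  1500, 0.020, c(50, 200, 700, 1500), c(200, 110, 50, 50),
        c(1.05, 0.90, 0.90, 1.10)),
    ref("ALOHA", 2000, 0.025, c(25, 75, 500, 4000), c(200, 200, 50, 110),
        c(1.10, 0.95, 0.95, 1.05)),
    ref("BATS",  1800, 0.030, c(10, 100, 250, 500), c(200, 200, 110, 50),
        c(1.00, 0.85, 0.85, 1.00)),
    tibble(site = "Iquique", role = "omz",
           depth_m = c(50, 85, 110, 200),
           par_surface = 1200, attenuation_k = 0.10,
           do_umol_kg = c(25, 11, 4, 3.2),
           lambda = c(0.39, 0.26, 0, 0),
           effect_scale = c(1.00, 1.00, 0.95, 1.05)),
    tibble(site = c("GOS1", "GOS2", "GOS3", "GOS4", "MedSea", "RedSea",
                    "Marmara", "PRT"),
           role = "single",
           depth_m = c(2, 2, 2, 2, 50, 10, 1000, 6000),
           par_surface = c(2000, 2000, 2000, 2000, 2000, 2100, 1600, 2000),
           attenuation_k = c(0.04, 0.04, 0.04, 0.04, 0.03, 0.05, 0.05, 0.04),
           do_umol_kg = c(200, 200, 200, 200, 200, 200, 30, 110),
           lambda = c(NA, NA, NA, NA, NA, NA, 0.33, NA),
           effect_scale = c(1.00, 1.05, 0.95, 1.00, 0.90, 1.00, 1.00, 1.00))
  )
  design |>
    mutate(dataset_id = sprintf("%s_%gm", .data$site, .data$depth_m)) |>
    select("dataset_id", everything())
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic depth-stratified
#' metagenome generator. The defaults are the reference configuration:
#' 2000 background COGs, 54 photic and 28 aphotic planted markers at fold
#' change 4, 18 oxygen-responsive markers switching on at dissolved oxygen
#' <= 11 µmol/kg, libraries of 50-60k assigned reads, and the 24-dataset
#' design of [reference_design()].
#'
#' @param n_background_cogs Number of unplanted background COGs.
#' @param n_photic_markers,n_aphotic_markers Planted marker set sizes.
#' @param marker_fold_change Relative-abundance fold change of a marker in
#'   its "on" zone (> 1; exactly 1 disables the effect, giving null data
#'   for calibration runs).
#' @param n_o2_markers Number of oxygen-responsive markers.
#' @param o2_threshold Dissolved oxygen (µmol/kg) at or below which the
#'   oxygen markers switch on.
#' @param o2_fold_change Fold change of the oxygen markers when on (>= 1).
#' @param design Dataset design tibble (see [reference_design()]).
#' @param library_size_range Two positive integers; each dataset's library
#'   size is drawn uniformly from this range.
#' @param dirichlet_concentration Concentration of the per-dataset Dirichlet
#'   perturbation of the base composition (larger = less site-to-site
#'   compositional noise; `Inf` disables the perturbation so counts are
#'   exactly multinomial from the base composition, the sampling model the
#'   per-column exact tests assume).
#' @param base_abundance_sdlog SD of the log-normal base COG abundances.
#'   The mild default (0.25) keeps every COG, markers included, within the
#'   abundance range where a 50k-read library carries signal; real COG
#'   abundance distributions are far heavier-tailed.
#' @param phylum_profiles Named list of per-marker-class phylum
#'   distributions (`photic`, `aphotic`, `o2`, `background`), each a named
#'   probability vector over phylum names.
#' @param eukarya_fraction Fraction of reads labelled Eukarya (discarded by
#'   the taxonomy stage).
#' @param unidentified_fraction Fraction of reads with no confident
#'   taxonomic label.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_cogs = 2000,
                       n_photic_markers = 54,
                       n_aphotic_markers = 28,
                       marker_fold_change = 4,
                       n_o2_markers = 18,
                       o2_threshold = 11,
                       o2_fold_change = 4,
                       design = reference_design(),
                       library_size_range = c(50000, 60000),
                       dirichlet_concentration = 1e5,
                       base_abundance_sdlog = 0.25,
                       phylum_profiles = default_phylum_profiles(),
                       eukarya_fraction = 0.05,
                       unidentified_fraction = 0.02) {
  cfg <- list(n_background_cogs = n_background_cogs,
              n_photic_markers = n_photic_markers,
              n_aphotic_markers = n_aphotic_markers,
              marker_fold_change = marker_fold_change,
              n_o2_markers = n_o2_markers,
              o2_threshold = o2_threshold,
              o2_fold_change = o2_fold_change,
              design = design,
              library_size_range = as.integer(library_size_range),
              dirichlet_concentration = dirichlet_concentration,
              base_abundance_sdlog = base_abundance_sdlog,
              phylum_profiles = phylum_profiles,
              eukarya_fraction = eukarya_fraction,
              unidentified_fraction = unidentified_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ints <- c("n_background_cogs", "n_photic_markers", "n_aphotic_markers",
            "n_o2_markers")
  for (nm in ints) {
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) {
      stop_validation("%s must be a positive integer", nm)
    }
  }
  if (cfg$marker_fold_change < 1 || cfg$o2_fold_change < 1) {
    stop_validation("fold changes must be >= 1")
  }
  if (cfg$o2_threshold <= 0) stop_validation("o2_threshold must be positive")
  d <- cfg$design
  need <- c("dataset_id", "site", "depth_m", "par_surface", "attenuation_k",
            "do_umol_kg", "lambda", "effect_scale")
  if (!all(need %in% names(d))) {
    stop_validation("design lacks column(s): %s",
                    paste(setdiff(need, names(d)), collapse = ", "))
  }
  lam <- d$lambda[!is.na(d$lambda)]
  if (any(lam < 0 | lam > 1)) stop_validation("lambda must lie in [0, 1]")
  if (length(cfg$library_size_range) != 2L || any(cfg$library_size_range < 1) ||
      cfg$library_size_range[1] > cfg$library_size_range[2]) {
    stop_validation("library_size_range must be an increasing positive pair")
  }
  if (cfg$dirichlet_concentration <= 0) {
    stop_validation("dirichlet_concentration must be positive")
  }
  if (cfg$eukarya_fraction < 0 || cfg$eukarya_fraction >= 1 ||
      cfg$unidentified_fraction < 0 ||
      cfg$eukarya_fraction + cfg$unidentified_fraction >= 1) {
    stop_validation("eukarya/unidentified fractions must leave mass for labelled reads")
  }
  invisible(cfg)
}

#' Default per-marker-class phylum profiles
#'
#' The photic marker profile concentrates ~91% of reads in two phyla
#' (Proteobacteria and Cyanobacteria, the two dominating sunlit marine
#' communities); the aphotic and oxygen-marker profiles spread reads over
#' ten phyla; the background profile is intermediate.
#'
#' @return Named list of named probability vectors.
#' @export
default_phylum_profiles <- function() {
  aphotic <- c(Proteobacteria = 0.50, Chloroflexi = 0.08, Bacteroidetes = 0.07,
               Actinobacteria = 0.06, Firmicutes = 0.06, Planctomycetes = 0.05,
               Thaumarchaeota = 0.05, Euryarchaeota = 0.05,
               Verrucomicrobia = 0.04, Acidobacteria = 0.04)
  list(
    photic = c(Proteobacteria = 0.46, Cyanobacteria = 0.45,
               Bacteroidetes = 0.04, Actinobacteria = 0.03, Firmicutes = 0.02),
    aphotic = aphotic,
    o2 = aphotic,
    background = c(Proteobacteria = 0.40, Cyanobacteria = 0.15,
                   Bacteroidetes = 0.12, Actinobacteria = 0.10,
                   Firmicutes = 0.08, Planctomycetes = 0.05, Chloroflexi = 0.04,
                   Euryarchaeota = 0.03, Thaumarchaeota = 0.02,
                   Verrucomicrobia = 0.01)
  )
}

.archaeal_phyla <- c("Thaumarchaeota", "Euryarchaeota", "Crenarchaeota")

# Expected relative COG composition of one dataset.
# p0: Dirichlet-perturbed base composition; class: per-COG class factor;
# lambda: weight on the photic community; o2_on: oxygen markers switched on;
# scale: per-dataset effect modifier (fold^scale).
dataset_composition <- function(p0, class, lambda, o2_on, cfg, scale = 1) {
  f <- cfg$marker_fold_change^scale
  photic_comp <- p0
  photic_comp[class == "photic"] <- photic_comp[class == "photic"] * f
  photic_comp <- photic_comp / sum(photic_comp)
  aphotic_comp <- p0
  aphotic_comp[class == "aphotic"] <- aphotic_comp[class == "aphotic"] * f
  aphotic_comp <- aphotic_comp / sum(aphotic_comp)
  mix <- lambda * photic_comp + (1 - lambda) * aphotic_comp
  if (o2_on) {
    mix[class == "o2"] <- mix[class == "o2"] * cfg$o2_fold_change
  }
  mix / sum(mix)
}

#' Simulate a depth-stratified COG count study with planted truth
#'
#' Generates a COG count matrix, dataset metadata, a per-read taxonomy
#' table and the planted ground truth for the configured design. Per
#' dataset, a base log-normal COG composition is Dirichlet-perturbed
#' (site-to-site noise), planted photic/aphotic markers are multiplied by
#' the fold change in their "on" zone (mixed-layer datasets take a convex
#' combination of the pure photic and aphotic compositions with weight
#' `lambda`), oxygen markers are multiplied when dissolved oxygen is at or
#' below the threshold, and counts are drawn multinomially at a library
#' size drawn uniformly from the configured range. Identical seeds give
#' identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness is derived from it.
#' @param reads Generate the per-read taxonomy table? (Set `FALSE` to skip
#'   the largest output when only counts are needed.)
#' @return A list of class `cog_simulation` with elements `counts`
#'   (count tibble), `metadata` (metadata tibble with PAR fields filled and
#'   `zone_label` unset), `reads` (read-assignment tibble or `NULL`) and
#'   `truth` (planted marker ids, per-dataset zone and mixture weight, and
#'   the oxygen threshold).
#' @export
simulate_cog_data <- function(config = sim_config(), seed = 1, reads = TRUE) {
  cfg <- config
  validate_sim_config(cfg)
  withr::with_seed(seed, {
    n_bg <- cfg$n_background_cogs
    class <- factor(rep(c("background", "photic", "aphotic", "o2"),
                        c(n_bg, cfg$n_photic_markers, cfg$n_aphotic_markers,
                          cfg$n_o2_markers)),
                    levels = c("background", "photic", "aphotic", "o2"))
    m <- length(class)
    cog_ids <- sprintf("COG%04d", seq_len(m))
    base_w <- rlnorm(m, 0, cfg$base_abundance_sdlog)
    base_p <- base_w / sum(base_w)

    d <- cfg$design
    par_depth <- par_at_depth(d$par_surface, d$attenuation_k, d$depth_m)
    photic_truth <- par_depth >= 0.01 * d$par_surface
    lambda <- ifelse(is.na(d$lambda), as.numeric(photic_truth), d$lambda)
    o2_on <- d$do_umol_kg <= cfg$o2_threshold

    lo <- cfg$library_size_range[1]; hi <- cfg$library_size_range[2]
    libs <- if (lo == hi) rep(lo, nrow(d)) else lo + sample.int(hi - lo + 1L, nrow(d), replace = TRUE) - 1L

    counts <- matrix(0L, m, nrow(d), dimnames = list(cog_ids, d$dataset_id))
    for (j in seq_len(nrow(d))) {
      p0 <- if (is.infinite(cfg$dirichlet_concentration)) {
        base_p
      } else {
        g <- rgamma(m, shape = base_p * cfg$dirichlet_concentration)
        g / sum(g)
      }
      comp <- dataset_composition(p0, class, lambda[j], o2_on[j], cfg,
                                  scale = d$effect_scale[j])
      counts[, j] <- rmultinom(1, libs[j], comp)[, 1]
    }

    metadata <- tibble(
      dataset_id = d$dataset_id, site = d$site, depth_m = d$depth_m,
      do_umol_kg = d$do_umol_kg, par_surface = d$par_surface,
      par_at_depth = par_depth, attenuation_k = d$attenuation_k,
      zone_label = "unset")

    truth <- list(
      photic_marker_ids = cog_ids[class == "photic"],
      aphotic_marker_ids = cog_ids[class == "aphotic"],
      o2_marker_ids = cog_ids[class == "o2"],
      zone = setNames(ifelse(photic_truth, "photic", "aphotic"), d$dataset_id),
      lambda = setNames(lambda, d$dataset_id),
      o2_on = setNames(o2_on, d$dataset_id),
      o2_threshold = cfg$o2_threshold)

    reads_tbl <- NULL
    if (reads) {
      reads_tbl <- simulate_reads(counts, class, cfg)
    }
    structure(list(counts = as_count_tbl(counts), metadata = metadata,
                   reads = reads_tbl, truth = truth, config = cfg),
              class = "cog_simulation")
  })
}

simulate_reads <- function(counts, class, cfg) {
  profiles <- cfg$phylum_profiles
  per_ds <- lapply(colnames(counts), function(ds) {
    n <- counts[, ds]
    tot <- sum(n)
    cog <- rep(rownames(counts), n)
    cls <- as.character(rep(class, n))
    phylum <- character(tot)
    for (cl in unique(cls)) {
      sel <- cls == cl
      prof <- profiles[[cl]]
      phylum[sel] <- sample(names(prof), sum(sel), replace = TRUE, prob = prof)
    }
    u <- runif(tot)
    euk <- u < cfg$eukarya_fraction
    unid <- !euk & u < cfg$eukarya_fraction + cfg$unidentified_fraction
    superkingdom <- ifelse(phylum %in% .archaeal_phyla, "Archaea", "Bacteria")
    superkingdom[euk] <- "Eukarya"; phylum[euk] <- "Eukarya_phylum"
    superkingdom[unid] <- "unidentified"; phylum[unid] <- NA_character_
    tibble(read_id = sprintf("%s_r%06d", ds, seq_len(tot)),
           dataset_id = ds, cog_id = cog,
           superkingdom = superkingdom, phylum = phylum)
  })
  bind_rows(per_ds)
}

#' @export
print.cog_simulation <- function(x, ...) {
  cat("Synthetic COG study:", ncol(x$counts) - 1L, "datasets,",
      nrow(x$counts), "COGs\n")
  cat("  planted markers:", length(x$truth$photic_marker_ids), "photic,",
      length(x$truth$aphotic_marker_ids), "aphotic,",
      length(x$truth$o2_marker_ids), "oxygen-responsive (threshold",
      x$truth$o2_threshold, "µmol/kg)\n")
  invisible(x)
}
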