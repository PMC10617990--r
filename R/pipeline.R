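# End-to-end orchestration: a synthetic study generator (contours, layered
# images, tree, traits, ground truth), the per-section morphometry pipeline
# and the comparative pipeline, all driven by one seeded configuration and
# writing provenance manifests.

#' Generate a complete synthetic study on disk
#'
#' A miniature multi-species study exercising every stage: one folded
#' contour and one layered section image per species (written as JSON and
#' PNG), a pure-birth ultrametric tree (Newick), a correlated BM trait
#' table (CSV), a section table with per-section scale bars, and a ground
#' truth JSON holding the generating parameters.
#'
#' @param dir output directory.
#' @param seed master seed; all per-species seeds derive from it.
#' @param n_species number of species.
#' @param with_images also render section images (the slow part).
#' @return invisible list with the study file paths and the truth list.
#' @export
generate_synthetic_study <- function(dir, seed, n_species = 12L,
                                     with_images = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  par <- with_seed(seed, data.frame(
    species = sprintf("sp%0*d", nchar(as.character(n_species)),
                      seq_len(n_species)),
    radius = exp(stats::runif(n_species, log(1.2), log(2.5))),
    n_folds = sample(4:12, n_species, replace = TRUE),
    rel_amp = stats::runif(n_species, 0.06, 0.18),
    noise = stats::runif(n_species, 0, 0.03),
    thickness = stats::runif(n_species, 0.1, 0.25),
    mm_per_px = 0.012,
    seed = sample.int(1e6, n_species)))
  truth <- list(seed = seed, species = list())
  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    p <- par[i, ]
    fc <- generate_folded_contour(p$radius, p$n_folds,
                                  p$rel_amp * p$radius,
                                  noise_sd = p$noise * p$rel_amp * p$radius,
                                  mm_per_px = p$mm_per_px, seed = p$seed,
                                  label = "cerebellum")
    cfile <- file.path(dir, paste0(p$species, "_contour.json"))
    write_contour_annotation(fc$contour, cfile)
    ifile <- NA_character_
    if (with_images) {
      li <- generate_layered_section_image(fc$contour, p$thickness,
                                           blur_sd = 1, noise_sd = 0.02,
                                           seed = p$seed)
      ifile <- file.path(dir, paste0(p$species, "_section.png"))
      write_section_png(li$image, ifile)
    }
    # per-section scale bar reproducing the species' calibration
    rows[[i]] <- data.frame(species = p$species,
                            contour = basename(cfile),
                            image = basename(ifile),
                            scalebar_px = 1000,
                            scalebar_mm = 1000 * p$mm_per_px)
    truth$species[[p$species]] <- list(
      n_folds = p$n_folds,
      radius = p$radius,
      amplitude = p$rel_amp * p$radius,
      thickness = p$thickness,
      median_chord = stats::median(fc$folia$chord),
      median_arc = stats::median(fc$folia$arc),
      perimeter = fc$params$perimeter_true)
  }
  sections <- do.call(rbind, rows)
  utils::write.csv(sections, file.path(dir, "sections.csv"),
                   row.names = FALSE)
  tree <- generate_tree(n_species, depth = 180, seed = seed)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  m <- 4L
  Rtrue <- with_seed(seed + 1L, {
    W <- stats::rWishart(1L, df = 3L * m, Sigma = diag(m))[, , 1L]
    stats::cov2cor(W) * 0.02   # BM rate per My on log10 scale
  })
  traits <- simulate_traits(tree, "BM", R = Rtrue, root_state = 1,
                            seed = seed + 2L)
  write_trait_table(traits, file.path(dir, "traits.csv"))
  truth$trait_model <- list(model = "BM", R = Rtrue, root_state = 1)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(dir = dir,
                 sections = file.path(dir, "sections.csv"),
                 tree = file.path(dir, "tree.nwk"),
                 traits = file.path(dir, "traits.csv"),
                 truth = truth))
}

#' Run the per-section morphometry pipeline
#'
#' For every row of the study's section table: read and calibrate the
#' contour, measure section metrics and folia; when an image is present
#' and passes the pixel-density QC, estimate molecular-layer thickness.
#' Per-section failures are logged and leave missing cells rather than
#' aborting the run.
#'
#' @param study_dir directory produced by [generate_synthetic_study()] (or
#'   hand-assembled with the same layout: `sections.csv` plus the files it
#'   names).
#' @param spacing,classifier passed to [measure_contour()].
#' @param qc_threshold minimum mask pixels per mm^2 for thickness.
#' @param out_dir optional directory for CSV + manifest output.
#' @param thickness_args list of overrides for [measure_thickness()].
#' @return data frame, one row per section.
#' @export
run_section_pipeline <- function(study_dir, spacing = 0.05,
                                 classifier = "rule", qc_threshold = 3.5,
                                 out_dir = NULL, thickness_args = list()) {
  sec_file <- file.path(study_dir, "sections.csv")
  if (!file.exists(sec_file)) stop("no sections.csv in ", study_dir)
  sections <- utils::read.csv(sec_file, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(sections))
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    row <- data.frame(species = s$species, area = NA_real_,
                      length = NA_real_, gyrification = NA_real_,
                      n_folia = NA_integer_, median_width = NA_real_,
                      median_perimeter = NA_real_, qc_density = NA_real_,
                      qc_pass = NA, thickness = NA_real_,
                      error = "")
    res <- tryCatch({
      ct <- read_contour_annotation(file.path(study_dir, s$contour),
                                    "cerebellum")
      ct <- calibrate_scale(ct, s$scalebar_px, s$scalebar_mm)
      mc <- measure_contour(ct, spacing = spacing, classifier = classifier)
      row$area <- mc$metrics$area
      row$length <- mc$metrics$length
      row$gyrification <- mc$metrics$gyrification
      row$n_folia <- mc$folia$n_folia
      row$median_width <- mc$folia$median_width
      row$median_perimeter <- mc$folia$median_perimeter
      if (!is.na(s$image) && nzchar(s$image) &&
          file.exists(file.path(study_dir, s$image))) {
        px <- read_section_png(file.path(study_dir, s$image))
        img <- section_image(px, ct$mm_per_px, ct)
        qc <- qc_pixel_density(img, section_area_mm2 = mc$metrics$area,
                               threshold = qc_threshold)
        row$qc_density <- qc$density
        row$qc_pass <- qc$pass
        if (qc$pass) {
          th <- do.call(measure_thickness, c(list(img), thickness_args))
          row$thickness <- th$estimate$thickness_mm
        }
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      message("section ", s$species, " failed: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write_results(list(section_morphometry = out), out_dir,
                  config = list(spacing = spacing, classifier = classifier,
                                qc_threshold = qc_threshold))
  out
}

#' Run the comparative pipeline
#'
#' Fits the requested trait-evolution models, ranks them by AICc, and runs
#' the phylogenetically conditioned statistics under the winning model:
#' evolutionary covariance with partial correlations and edge-exclusion
#' tests, phylogenetic PCA, pairwise multivariate allometric slopes, and
#' ancestral states of the first two PC scores.
#'
#' @param tree a `phylo` tree or path to a Newick file.
#' @param traits trait matrix or path to a trait CSV.
#' @param models character subset of `c("BM", "OU", "EB")`.
#' @param restarts,seed OU fitting controls.
#' @param out_dir optional directory for CSV + manifest output.
#' @return list with `fits`, `ranking`, `best`, `covariance`, `pca`,
#'   `allometry_ma`, `ancestral`.
#' @export
run_comparative_pipeline <- function(tree, traits,
                                     models = c("BM", "OU", "EB"),
                                     restarts = 5L, seed = 1L,
                                     out_dir = NULL) {
  if (is.character(tree)) tree <- read_newick_tree(tree)
  if (is.character(traits)) traits <- read_trait_table(traits)
  models <- match.arg(models, c("BM", "OU", "EB"), several.ok = TRUE)
  mt <- match_tree_traits(tree, as.matrix(traits))
  X <- complete_trait_cases(mt$traits)
  if (nrow(X) < nrow(mt$traits))
    mt <- match_tree_traits(ape::keep.tip(mt$tree, rownames(X)), X)
  fits <- lapply(models, function(mdl)
    fit_evo(mt$tree, mt$traits, mdl, restarts = restarts, seed = seed))
  names(fits) <- models
  ranking <- aicc_rank(fits)
  best <- fits[[ranking$model[1L]]]
  ec <- evolutionary_covariance(mt$tree, mt$traits, best)
  pca <- phylo_pca(mt$tree, mt$traits, best)
  tn <- colnames(mt$traits)
  pairs <- t(utils::combn(tn, 2L))
  ma <- data.frame(trait_a = pairs[, 1L], trait_b = pairs[, 2L])
  ma$slope_ma <- apply(pairs, 1L, function(pr)
    allometry_multivariate(pca, pr[1L], pr[2L]))
  anc <- lapply(c("PC1", "PC2")[seq_len(min(2L, ncol(pca$scores)))],
                function(pc) ancestral_states(mt$tree, pca$scores[, pc],
                                              best))
  names(anc) <- c("PC1", "PC2")[seq_along(anc)]
  out <- list(fits = fits, ranking = ranking, best = best,
              covariance = ec, pca = pca, allometry_ma = ma,
              ancestral = anc)
  if (!is.null(out_dir)) {
    tables <- list(
      model_ranking = ranking,
      pcorr = as.data.frame(ec$pcorr),
      pcorr_pvalues = as.data.frame(ec$pvalues),
      pca_loadings = as.data.frame(pca$loadings),
      pca_scores = as.data.frame(pca$scores),
      pca_variance = data.frame(component = seq_along(pca$variance_fraction),
                                fraction = pca$variance_fraction),
      allometry_multivariate = ma)
    for (nm in names(anc))
      tables[[paste0("ancestral_", nm)]] <- anc[[nm]]
    write_results(tables, out_dir,
                  config = list(models = models, restarts = restarts),
                  seeds = c(seed = seed))
  }
  out
}
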