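# End-to-end pipeline: base level -> ion clipping -> wavelet filter ->
# per-frame threshold -> candidates (watershed) -> region extraction ->
# sub-pixel fit (optionally multi-emitter) -> duplicate removal ->
# intensity filter -> photon-image accumulation and FPN.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_init_sd <- c(mle_gauss = 1.0, ls_gauss = 1.0, wls_igauss = 1.6,
                     centroid = NA_real_, radial = NA_real_)

#' Pipeline configuration
#'
#' Returns the full parameter set of [run_pipeline()], starting from one of
#' two presets and applying any overrides.  The presets carry the tuned
#' parameter sets of the reference EBCCD acquisitions:
#'
#' * `"usaf"` — sparse transmission imaging (~150 events/frame): PIT
#'   multiplier 2, intensity filter > 4000 pe.
#' * `"cell"` — denser fluorescence imaging (~460 events/frame): PIT
#'   multiplier 1.5, intensity filter > 3000 pe.
#'
#' Both use wavelet order 3 / scale 2, watershed on, ML Gaussian fitting
#' with initial SD 1.0 px and fitting radius 2 px, ion clipping with 5 %
#' headroom, and (when multi-emitter fitting is enabled) duplicate removal
#' at 160 nm followed by the intensity filter — in that order.
#'
#' @param preset `"usaf"` or `"cell"`.
#' @param ... Overrides; top-level scalar fields replace, list fields (e.g.
#'   `detect`, `fit`, `mfa`) are merged element-wise.
#' @return A list of class `ebc_config`.
#' @examples
#' pipeline_config("usaf", fit = list(radius = 7), mfa = list(enabled = TRUE))
#' @export
pipeline_config <- function(preset = c("usaf", "cell"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    detect = list(order = 3, scale = 2,
                  pit_multiplier = if (preset == "usaf") 2 else 1.5,
                  watershed = TRUE),
    fit = list(method = "mle_gauss", radius = 2L, init_sd = NULL,
               sigma_bounds = c(0.3, 3), fix_sigma = FALSE),
    mfa = list(enabled = FALSE, max_emitters = 2L, p_threshold = 1e-6),
    clip_ions = TRUE, ion_epsilon = 0.05,
    photon_max = NULL, photon_max_quantile = 0.999,
    base_level_adu = NULL,
    remove_duplicates = NULL,        # NULL: follow mfa$enabled
    duplicate_nm = 160,
    apply_intensity_filter = NULL,   # NULL: follow mfa$enabled
    min_intensity_pe = if (preset == "usaf") 4000 else 3000,
    chunk_size = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  if (!cfg$fit$method %in% names(default_init_sd))
    stop("config error: unknown fit method '", cfg$fit$method, "'")
  class(cfg) <- "ebc_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' The file may contain a `preset` key plus any [pipeline_config()] fields.
#'
#' @param path JSON file path.
#' @return An `ebc_config` list.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- j$preset %||% "usaf"
  j$preset <- NULL
  do.call(pipeline_config, c(list(preset = preset), j))
}

#' Localise one fitting region with a named method
#'
#' Thin dispatcher over the five sub-pixel localisers; methods that signal
#' degenerate input return a rejected (`ok = FALSE`) row instead of
#' stopping.
#'
#' @param region An [extract_region()] region.
#' @param method One of `"mle_gauss"`, `"ls_gauss"`, `"wls_igauss"`,
#'   `"centroid"`, `"radial"`.
#' @param init_sd Initial fitted SD (px); method-specific default if `NULL`.
#' @param sigma_bounds,fix_sigma Passed to the fitting methods.
#' @return One-row localisation data frame.
#' @export
localise_region <- function(region, method = "mle_gauss", init_sd = NULL,
                            sigma_bounds = c(0.3, 3), fix_sigma = FALSE) {
  sd0 <- init_sd %||% unname(default_init_sd[method])
  res <- tryCatch(switch(
    method,
    mle_gauss = fit_gaussian_mle(region, sd0, sigma_bounds, fix_sigma),
    ls_gauss = fit_gaussian_ls(region, sd0, sigma_bounds, fix_sigma),
    wls_igauss = fit_integrated_gaussian_wls(region, sd0, sigma_bounds,
                                             fix_sigma),
    centroid = localise_local_centroid(region),
    radial = localise_radial_symmetry(region),
    stop("unknown method: ", method)),
    error = function(e)
      loc_row(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, method,
              NA_real_, converged = FALSE, ok = FALSE))
  res
}

#' Run the full photon-counting centroiding pipeline
#'
#' Processes a frame stack in the stage order: per-chunk base-level
#' estimation, ion clipping, B-spline wavelet filtering, per-frame adaptive
#' thresholding, connected-component candidates with watershed, region
#' extraction, sub-pixel fitting (multi-emitter if enabled), duplicate
#' removal, intensity filtering, and accumulation into 1-pixel and
#' 1/5-pixel photon images with the FPN diagnostic.  Deterministic: all
#' randomness lives in the simulator.
#'
#' @param stack An [frame_stack()], an [simulate_stack()] result, or a path
#'   to a multi-page TIFF.
#' @param config An [pipeline_config()] list.
#' @param verbose Print per-chunk progress?
#' @return An object of class `ebc_result`: list with `localisations` (data
#'   frame incl. `x_nm`/`y_nm`/`sigma_nm`), `image_px1`, `image_px5`
#'   (photon images), `occupancy5`, `occupancy13`, `fpn` (percent), `log`
#'   (stage counts), `config`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(), verbose = FALSE) {
  if (is.character(stack)) stack <- read_tiff_stack(stack)
  if (inherits(stack, "ebc_simulation")) stack <- stack$stack
  stopifnot(inherits(stack, "ebc_stack"), inherits(config, "ebc_config"))
  calib <- stack$calibration
  frames <- stack$frames
  nfr <- length(frames)
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  chunk <- config$chunk_size %||% nfr
  starts <- seq(1L, nfr, by = chunk)
  mfa_on <- isTRUE(config$mfa$enabled)
  log <- list(frames = nfr, candidates = 0L, fitted = 0L, rejected = 0L,
              mfa_splits = 0L, duplicates_removed = 0L,
              intensity_filtered = 0L, base_levels = numeric(0))
  locs <- list()
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nfr)
    chunk_frames <- frames[idx]
    base <- config$base_level_adu %||% calib$base_level_adu %||%
      estimate_base_level(chunk_frames)
    log$base_levels <- c(log$base_levels, base)
    photon_max <- NULL
    if (isTRUE(config$clip_ions))
      photon_max <- config$photon_max %||%
        tryCatch(estimate_photon_event_max(chunk_frames,
                                           config$photon_max_quantile),
                 error = function(e) NULL)
    for (k in seq_along(idx)) {
      f <- chunk_frames[[k]]
      if (!is.null(photon_max) && photon_max > base)
        f <- clip_ion_events(f, photon_max, config$ion_epsilon)
      filt <- wavelet_filter(f, config$detect$order, config$detect$scale)
      thr <- detection_threshold(filt, config$detect$pit_multiplier)
      cand <- find_candidates(filt, thr, config$detect$watershed)
      log$candidates <- log$candidates + nrow(cand)
      if (nrow(cand) == 0L) next
      pe <- adu_to_photoelectrons(f, calib, base)
      for (i in seq_len(nrow(cand))) {
        region <- extract_region(pe, cand$cx[i], cand$cy[i],
                                 config$fit$radius)
        li <- if (mfa_on)
          fit_multi(region, config$mfa$max_emitters, config$mfa$p_threshold,
                    config$fit$init_sd %||% 1.0, config$fit$sigma_bounds)
        else
          localise_region(region, config$fit$method, config$fit$init_sd,
                          config$fit$sigma_bounds, config$fit$fix_sigma)
        log$fitted <- log$fitted + nrow(li)
        log$rejected <- log$rejected + sum(!li$ok)
        if (mfa_on && nrow(li) == 2L)
          log$mfa_splits <- log$mfa_splits + 1L
        li <- li[li$ok, , drop = FALSE]
        if (nrow(li)) {
          li$frame <- idx[k]
          locs[[length(locs) + 1L]] <- li
        }
      }
    }
    if (verbose)
      message(sprintf("chunk %d-%d: base %.1f ADU, %d localisations so far",
                      idx[1L], idx[length(idx)], base,
                      sum(vapply(locs, nrow, integer(1)))))
  }
  locs <- if (length(locs)) do.call(rbind, locs) else
    data.frame(x_px = numeric(0), y_px = numeric(0),
               intensity_pe = numeric(0), sigma_px = numeric(0),
               background_pe = numeric(0), method = character(0),
               n_emitters = integer(0), objective = numeric(0),
               converged = logical(0), ok = logical(0), frame = integer(0))
  if (nrow(locs) == 0L)
    warning("pipeline produced zero localisations; check threshold settings")
  locs$x_nm <- locs$x_px * calib$pixel_size_nm
  locs$y_nm <- locs$y_px * calib$pixel_size_nm
  locs$sigma_nm <- locs$sigma_px * calib$pixel_size_nm
  if (isTRUE(config$remove_duplicates %||% mfa_on)) {
    n0 <- nrow(locs)
    locs <- remove_duplicates(locs, config$duplicate_nm)
    log$duplicates_removed <- n0 - nrow(locs)
  }
  if (isTRUE(config$apply_intensity_filter %||% mfa_on)) {
    n0 <- nrow(locs)
    locs <- filter_intensity(locs, config$min_intensity_pe)
    log$intensity_filtered <- n0 - nrow(locs)
  }
  log$accepted <- nrow(locs)
  img1 <- accumulate_image(locs, c(w, h), 1L)
  img5 <- accumulate_image(locs, c(w, h), 5L)
  occ5 <- subpixel_occupancy(locs, 5L)
  occ13 <- subpixel_occupancy(locs, 13L)
  fpn <- if (nrow(locs)) compute_fpn(occ5) else NA_real_
  structure(list(localisations = locs, image_px1 = img1, image_px5 = img5,
                 occupancy5 = occ5, occupancy13 = occ13, fpn = fpn,
                 log = log, config = config),
            class = "ebc_result")
}

#' @export
print.ebc_result <- function(x, ...) {
  cat(sprintf("EBCCD centroiding result: %d localisations from %d frames\n",
              nrow(x$localisations), x$log$frames))
  cat(sprintf("  method %s, radius %d px, MFA %s\n", x$config$fit$method,
              x$config$fit$radius,
              if (isTRUE(x$config$mfa$enabled)) "on" else "off"))
  cat(sprintf("  FPN (5x5 subpixel array): %.1f %%\n", x$fpn))
  invisible(x)
}

#' @export
summary.ebc_result <- function(object, ...) {
  l <- object$log
  cat("pipeline stage counts\n")
  cat(sprintf("  frames               %d\n", l$frames))
  cat(sprintf("  base level(s) [ADU]  %s\n",
              paste(sprintf("%.1f", l$base_levels), collapse = ", ")))
  cat(sprintf("  candidates           %d\n", l$candidates))
  cat(sprintf("  fits returned        %d\n", l$fitted))
  cat(sprintf("  fits rejected        %d\n", l$rejected))
  cat(sprintf("  MFA splits           %d\n", l$mfa_splits))
  cat(sprintf("  duplicates removed   %d\n", l$duplicates_removed))
  cat(sprintf("  intensity-filtered   %d\n", l$intensity_filtered))
  cat(sprintf("  accepted             %d\n", l$accepted))
  cat(sprintf("  FPN                  %.1f %%\n", object$fpn))
  invisible(l)
}

#' @export
plot.ebc_result <- function(x, which = c("image", "occupancy"), ...) {
  which <- match.arg(which)
  if (which == "image") {
    img <- x$image_px5
    graphics::image(t(img)[, nrow(img):1],
                    col = grDevices::grey.colors(256, 0, 1),
                    axes = FALSE, main = "1/5-pixel photon image", ...)
  } else {
    occ <- x$occupancy13
    graphics::image(t(occ)[, nrow(occ):1],
                    col = grDevices::grey.colors(256, 0, 1),
                    axes = FALSE, main = "13x13 centroid-position distribution",
                    ...)
  }
  invisible(x)
}

#' Write a localisation table as CSV
#'
#' Column layout follows common localisation-table conventions:
#' `frame, x_nm, y_nm, sigma_nm, intensity_pe, background_pe, method,
#' n_emitters, objective`.
#'
#' @param locs Localisation data frame (e.g. `result$localisations`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localisations <- function(locs, path) {
  cols <- c("frame", "x_nm", "y_nm", "sigma_nm", "intensity_pe",
            "background_pe", "method", "n_emitters", "objective")
  utils::write.csv(locs[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Match localisations to ground truth
#'
#' Greedy nearest-neighbour matching per frame within a tolerance radius;
#' each truth event and each localisation is used at most once.
#'
#' @param locs Localisation data frame (`frame`, `x_px`, `y_px`).
#' @param truth Ground-truth data frame (`frame`, `x_px`, `y_px`), e.g.
#'   `simulate_stack()$truth` (usually restricted to `kind == "photon"`).
#' @param radius_px Match tolerance (px).
#' @return List: `matches` (data frame `truth_row`, `loc_row`, `dist_px`),
#'   `recall`, `false_rate` (fraction of unmatched localisations),
#'   `rmse_px` (RMS matched distance).
#' @export
match_to_truth <- function(locs, truth, radius_px = 2) {
  matches <- list()
  for (fr in unique(truth$frame)) {
    ti <- which(truth$frame == fr)
    li <- which(locs$frame == fr)
    if (!length(li)) next
    dx <- outer(truth$x_px[ti], locs$x_px[li], `-`)
    dy <- outer(truth$y_px[ti], locs$y_px[li], `-`)
    dm <- sqrt(dx^2 + dy^2)
    repeat {
      j <- which.min(dm)
      if (!length(j) || dm[j] > radius_px) break
      r <- ((j - 1L) %% nrow(dm)) + 1L
      cl <- ((j - 1L) %/% nrow(dm)) + 1L
      matches[[length(matches) + 1L]] <-
        data.frame(truth_row = ti[r], loc_row = li[cl], dist_px = dm[j])
      dm[r, ] <- Inf
      dm[, cl] <- Inf
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(truth_row = integer(0), loc_row = integer(0),
               dist_px = numeric(0))
  list(matches = matches,
       recall = nrow(matches) / max(nrow(truth), 1L),
       false_rate = 1 - nrow(matches) / max(nrow(locs), 1L),
       rmse_px = if (nrow(matches)) sqrt(mean(matches$dist_px^2)) else NA_real_)
}

#' Score detection coverage against ground truth
#'
#' Hit-based detection metrics: a true event counts as detected if any
#' candidate lies within `radius_px` of it, and a candidate counts as false
#' if no true event lies within `radius_px` of it.  Unlike the one-to-one
#' matching of [match_to_truth()] (the right accounting for localisation
#' accuracy), this treats a merged pair of overlapping events as detected by
#' their common candidate region — separating them is the job of
#' multi-emitter fitting, not detection.
#'
#' @param cands Candidate data frame with `frame` and either `x_px`/`y_px`
#'   or `cx`/`cy` (integer pixel; centre `+0.5` is used).
#' @param truth Ground-truth data frame (`frame`, `x_px`, `y_px`).
#' @param radius_px Hit radius (px).
#' @return List with `recall` and `false_rate`.
#' @export
detection_score <- function(cands, truth, radius_px = 2) {
  if (is.null(cands$x_px)) {
    cands$x_px <- cands$cx + 0.5
    cands$y_px <- cands$cy + 0.5
  }
  hit <- 0L; nfalse <- 0L
  for (fr in unique(c(truth$frame, cands$frame))) {
    s <- truth[truth$frame == fr, , drop = FALSE]
    cc <- cands[cands$frame == fr, , drop = FALSE]
    if (nrow(cc) == 0L) next
    if (nrow(s) == 0L) { nfalse <- nfalse + nrow(cc); next }
    d2 <- outer(s$x_px, cc$x_px, `-`)^2 + outer(s$y_px, cc$y_px, `-`)^2
    hit <- hit + sum(apply(d2, 1L, min) <= radius_px^2)
    nfalse <- nfalse + sum(apply(d2, 2L, min) > radius_px^2)
  }
  list(recall = hit / max(nrow(truth), 1L),
       false_rate = nfalse / max(nrow(cands), 1L))
}

#' Benchmark centroiding methods on one stack
#'
#' Runs the pipeline once per method/radius combination and reports the
#' photon count, FPN and wall time (plus ground-truth recall when truth is
#' supplied).  Wall times are informative only.
#'
#' @param stack Frame stack, simulation, or TIFF path (see [run_pipeline()]).
#' @param methods Character vector of method names (see [localise_region()]).
#' @param radii Fitting radius per method (recycled).
#' @param config Base configuration.
#' @param truth Optional ground-truth data frame for recall.
#' @return Data frame: `method`, `radius`, `photons`, `fpn_percent`,
#'   `time_s`, and `recall` if truth was given.
#' @export
run_benchmark <- function(stack, methods = c("mle_gauss", "ls_gauss",
                                             "wls_igauss", "centroid",
                                             "radial"),
                          radii = c(2L, 2L, 3L, 2L, 2L),
                          config = pipeline_config(), truth = NULL) {
  if (length(methods) == 0L)
    return(data.frame(method = character(0), radius = integer(0),
                      photons = integer(0), fpn_percent = numeric(0),
                      time_s = numeric(0)))
  radii <- rep_len(radii, length(methods))
  if (inherits(stack, "ebc_simulation") && is.null(truth))
    truth <- stack$truth[stack$truth$kind == "photon", , drop = FALSE]
  rows <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    cfg <- config
    cfg$fit$method <- methods[i]
    cfg$fit$radius <- radii[i]
    cfg$fit$init_sd <- NULL
    t0 <- proc.time()[["elapsed"]]
    res <- run_pipeline(stack, cfg)
    dt <- proc.time()[["elapsed"]] - t0
    row <- data.frame(method = methods[i], radius = radii[i],
                      photons = nrow(res$localisations),
                      fpn_percent = res$fpn, time_s = dt)
    if (!is.null(truth))
      row$recall <- match_to_truth(res$localisations, truth)$recall
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
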