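#' End-to-end patient run: register, propagate, evaluate, accumulate dose
#'
#' For every guidance fraction: registers the guidance volume to the
#' planning volume, propagates the planning cord contours through the
#' recovered transform, and (when reference contours are supplied) scores
#' the auto-contours slice by slice. When per-fraction dose grids are
#' supplied, delivered dose is accumulated to the cord voxels through the
#' recovered transforms and summarised (D2%). A failure in one fraction is
#' recorded and does not abort the remaining fractions.
#'
#' @param kvct planning [image_volume].
#' @param cord_ss planning-frame [structure_set].
#' @param mvct_list list of guidance [image_volume]s.
#' @param references optional list of reference [structure_set]s (one per
#'   fraction, `NULL` entries allowed) to score auto-contours against.
#' @param dose_grids optional list of per-fraction dose [image_volume]s.
#' @param couch_shifts optional n x 3 matrix / list of recorded couch
#'   shifts; used by dose accumulation (composed after each transform).
#' @param config a [registration_config].
#' @param mask optional precomputed `binary_mask`; built from `kvct`
#'   otherwise.
#' @param pitch conformity raster pitch (mm).
#' @return A list with `transforms`, `auto_contours`, per-fraction
#'   `conformity_records`, pooled `conformity_summary`, `dose_map`,
#'   `dose_summary`, and `failures` (per-fraction error messages).
#' @export
run_patient <- function(kvct, cord_ss, mvct_list, references = NULL,
                        dose_grids = NULL, couch_shifts = NULL,
                        config = registration_config(), mask = NULL,
                        pitch = 0.1) {
  stopifnot_volume(kvct)
  if (!is_structure_set(cord_ss)) stop("expected a structure_set")
  nfrac <- length(mvct_list)
  if (nfrac < 1) stop("need at least one fraction")
  if (is.null(mask)) mask <- build_body_mask(kvct)

  transforms <- vector("list", nfrac)
  autos <- vector("list", nfrac)
  records <- vector("list", nfrac)
  failures <- list()
  for (f in seq_len(nfrac)) {
    res <- tryCatch({
      chain <- register(kvct, mvct_list[[f]], mask = mask, config = config)
      auto <- propagate_contours(cord_ss, chain, mvct_list[[f]])
      rec <- if (!is.null(references) && !is.null(references[[f]]))
        compare_structure_sets(auto, references[[f]], pitch = pitch)
      else NULL
      list(chain = chain, auto = auto, rec = rec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(fraction = f, message = conditionMessage(res))
      next
    }
    transforms[[f]] <- res$chain
    autos[[f]] <- res$auto
    records[[f]] <- if (is.null(res$rec)) NULL else
      cbind(fraction = f, res$rec)
  }

  all_rec <- do.call(rbind, records[!vapply(records, is.null, TRUE)])
  summary <- if (!is.null(all_rec) && nrow(all_rec) > 0)
    aggregate_conformity(all_rec, seed = config$seed) else NULL

  dose_map <- NULL
  dose_sum <- NULL
  if (!is.null(dose_grids)) {
    ok <- !vapply(transforms, is.null, TRUE)
    if (!all(ok))
      warning("dose accumulated over the ", sum(ok),
              " fraction(s) with a recovered transform")
    vox <- cord_voxels(cord_ss, kvct)
    cs <- couch_shifts
    if (!is.null(cs) && is.matrix(cs)) cs <- cs[ok, , drop = FALSE]
    else if (!is.null(cs)) cs <- cs[ok]
    dose_map <- accumulate_dose(vox, transforms[ok], dose_grids[ok],
                                couch_shifts = cs)
    dose_sum <- dvh_summary(dose_map)
  }

  list(transforms = transforms, auto_contours = autos,
       conformity_records = all_rec, conformity_summary = summary,
       dose_map = dose_map, dose_summary = dose_sum, failures = failures)
}

.strategy_names <- c("affine", "affine+bspline", "couch", "couch+bspline",
                     "rigid", "rigid+bspline", "translation",
                     "translation+bspline")

strategy_chain <- function(strategy, kvct, mvct, mask, couch_shift, config) {
  parts <- strsplit(strategy, "+", fixed = TRUE)[[1]]
  use_couch <- "couch" %in% parts
  stages <- setdiff(parts, "couch")
  init <- if (use_couch) {
    if (is.null(couch_shift)) stop("strategy '", strategy,
                                   "' needs a couch shift")
    couch_shift_transform(couch_shift)
  } else NULL
  if (length(stages) == 0) return(as_chain(init))
  cfg <- config
  cfg$stages <- stages
  cfg$initial_chain <- init
  register(kvct, mvct, mask = mask, config = cfg)
}

box_stats <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
             min = min(v), max = max(v))
}

#' Compare registration transform strategies
#'
#' Runs the eight transform strategies of the method study — affine, couch
#' shift, rigid (translations plus rotations) and translation, each alone
#' and each followed by a B-spline stage — on the same fractions, scoring
#' each strategy's auto-contours against the references.
#'
#' @inheritParams run_patient
#' @param couch_shifts n x 3 matrix (or list) of recorded radiographer
#'   couch shifts; required by the couch strategies.
#' @param strategies subset of
#'   `c("affine", "affine+bspline", "couch", "couch+bspline", "rigid",
#'   "rigid+bspline", "translation", "translation+bspline")`.
#' @return A list with per-strategy `summaries` ([aggregate_conformity()]
#'   outputs), `records`, and `box` — box-plot statistics (mean, median,
#'   quartiles, min, max) of the slice CI and DBC per strategy.
#' @export
strategy_comparison <- function(kvct, cord_ss, mvct_list, references,
                                strategies = .strategy_names,
                                couch_shifts = NULL,
                                config = registration_config(), mask = NULL,
                                pitch = 0.1) {
  unknown <- setdiff(strategies, .strategy_names)
  if (length(unknown) > 0)
    stop("unknown strategy name(s): ", paste(unknown, collapse = ", "))
  needs_couch <- any(grepl("couch", strategies))
  if (needs_couch && is.null(couch_shifts))
    stop("couch strategies requested but no couch shifts supplied")
  if (is.null(mask)) mask <- build_body_mask(kvct)
  if (!is.null(couch_shifts) && is.matrix(couch_shifts))
    couch_shifts <- lapply(seq_len(nrow(couch_shifts)),
                           function(i) couch_shifts[i, ])

  summaries <- list()
  all_records <- list()
  box <- list()
  for (s in strategies) {
    recs <- list()
    for (f in seq_along(mvct_list)) {
      shift <- if (is.null(couch_shifts)) NULL else couch_shifts[[f]]
      chain <- strategy_chain(s, kvct, mvct_list[[f]], mask, shift, config)
      auto <- propagate_contours(cord_ss, chain, mvct_list[[f]])
      recs[[f]] <- cbind(fraction = f,
                         compare_structure_sets(auto, references[[f]],
                                                pitch = pitch))
    }
    rec <- do.call(rbind, recs)
    all_records[[s]] <- rec
    summaries[[s]] <- aggregate_conformity(rec, seed = config$seed)
    box[[s]] <- cbind(strategy = s, metric = c("ci", "dbc"),
                      rbind(box_stats(rec$ci), box_stats(rec$dbc)))
  }
  list(summaries = summaries, records = all_records,
       box = do.call(rbind, box))
}

#' Sweep the B-spline control-point spacing
#'
#' Repeats affine + B-spline registration over a set of control-point
#' spacings and reports which spacing gives the highest mean conformity
#' index and which the smallest mean distance between centres.
#'
#' @inheritParams run_patient
#' @param spacings control-point spacings (mm) to try.
#' @return A list with per-spacing `summaries`, `records`, and `selection`
#'   (`best_ci_spacing`, `best_dbc_spacing`, and the per-spacing mean CI
#'   and DBC table).
#' @export
spacing_sweep <- function(kvct, cord_ss, mvct_list, references,
                          spacings = c(5, 10, 15, 20, 25),
                          config = registration_config(), mask = NULL,
                          pitch = 0.1) {
  if (length(spacings) == 0) stop("empty spacing list")
  if (any(spacings <= 0)) stop("spacings must be positive")
  if (is.null(mask)) mask <- build_body_mask(kvct)
  summaries <- list()
  records <- list()
  for (s in spacings) {
    cfg <- config
    cfg$stages <- c("affine", "bspline")
    cfg$cp_spacing <- s
    recs <- list()
    for (f in seq_along(mvct_list)) {
      chain <- register(kvct, mvct_list[[f]], mask = mask, config = cfg)
      auto <- propagate_contours(cord_ss, chain, mvct_list[[f]])
      recs[[f]] <- cbind(fraction = f,
                         compare_structure_sets(auto, references[[f]],
                                                pitch = pitch))
    }
    key <- as.character(s)
    records[[key]] <- do.call(rbind, recs)
    summaries[[key]] <- aggregate_conformity(records[[key]],
                                             seed = config$seed)
  }
  mean_ci <- vapply(records, function(r) mean(r$ci), 0)
  mean_dbc <- vapply(records, function(r) mean(r$dbc), 0)
  tab <- data.frame(spacing = spacings, mean_ci = mean_ci,
                    mean_dbc = mean_dbc)
  selection <- list(best_ci_spacing = spacings[which.max(mean_ci)],
                    best_dbc_spacing = spacings[which.min(mean_dbc)],
                    table = tab)
  list(summaries = summaries, records = records, selection = selection)
}
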