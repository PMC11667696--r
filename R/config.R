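# Configuration for scoring, ranking and batching. Defaults reproduce the
# published point tables; every knob can be overridden in code or via JSON.

#' sTILs density binning thresholds
#'
#' Densities are discretized as low (x <= `low_max_pct`), medium
#' (`low_max_pct` < x <= `medium_max_pct`) and high (x > `medium_max_pct`).
#'
#' @param low_max_pct Upper inclusive bound of the low bin (default 10).
#' @param medium_max_pct Upper inclusive bound of the medium bin (default 40).
#' @return A `density_binning` list.
#' @export
density_binning <- function(low_max_pct = 10, medium_max_pct = 40) {
  stopifnot(is.numeric(low_max_pct), is.numeric(medium_max_pct))
  if (!(0 < low_max_pct && low_max_pct < medium_max_pct &&
        medium_max_pct < 100))
    stop("need 0 < low_max_pct < medium_max_pct < 100", call. = FALSE)
  structure(list(low_max_pct = low_max_pct, medium_max_pct = medium_max_pct,
                 bins = .density_bins),
            class = "density_binning")
}

#' Default pitfall rarity map
#'
#' Points per pitfall label, tiered by how many cases (WSIs) a pitfall
#' appeared in: rare pitfalls score 2, semi-rare 1, common 0.
#'
#' @return Named integer vector, label -> points in \{0, 1, 2\}.
#' @seealso [derive_rarity_map()] to recompute the tiers on a new cohort.
#' @export
default_rarity_map <- function() {
  c("Carcinoma In Situ" = 2L, "Ischemia" = 2L, "Sparse Distribution" = 2L,
    "Fibers" = 2L, "Over Staining" = 2L, "Under Staining" = 2L,
    "Benign Glands" = 1L, "Necrosis/Fibrin" = 1L, "Eosinophilia" = 1L,
    "Perinuclear Clearing" = 1L, "Crush Artifact" = 1L,
    "Adipocytes" = 0L, "Nerves/Vessels" = 0L, "Pyknotic Nuclei" = 0L,
    "Fibroblasts" = 0L)
}

.default_age_points <- function() {
  data.frame(lower = c(0, 41, 51, 61, 71, 81, 91),
             upper = c(40, 50, 60, 70, 80, 90, Inf),
             points = c(2, 2, 1, 0, 1, 2, 2))
}

#' Prioritization configuration
#'
#' Collects every tunable of the rank-sort: density bin thresholds and
#' weights, the score point tables, the pitfall rarity map, batch geometry,
#' tie-breaking and the density-score denominator convention.
#'
#' @param binning A [density_binning()].
#' @param bin_weights Named weights of the density bins used in the
#'   normalized density count score (default low 0, medium 1, high 2).
#' @param denominator `"all"` (default): the density-score denominator is
#'   the total number of ROIs annotated on the WSI, not-evaluable ROIs
#'   included (they fall in no bin and add 0 to the numerator);
#'   `"evaluable"`: evaluable ROIs only.
#' @param stage_points Points per aggregated stage; missing stage scores 0.
#' @param age_points Data frame `lower`/`upper`/`points` of closed age
#'   ranges in whole years; ages above the last published range (90) score
#'   2 by default. Missing age scores 0.
#' @param sex_nonfemale_points Points when sex is present and not `"F"`.
#' @param rarity_map Named vector, pitfall label -> points.
#' @param derive_rarity If `TRUE`, recompute the rarity map from the cohort
#'   with [derive_rarity_map()] before scoring.
#' @param rare_max_cases,semirare_max_cases Case-count thresholds used when
#'   deriving the rarity map (rare: <= 2 cases, semi-rare: 3-10, common:
#'   more).
#' @param unlisted_pitfalls `"error"` (default): a pitfall label absent from
#'   the rarity map stops with an error naming it; `"zero"`: score it 0 with
#'   a warning.
#' @param batch_size Cases per batch (default 8).
#' @param n_batches Number of batches to fill (default 5).
#' @param tie_break Residual tie-break after all four scores; currently only
#'   `"wsi_id"` (ascending identifier order) is available.
#' @return A `prioritization_config` list.
#' @export
prioritization_config <- function(binning = density_binning(),
                                  bin_weights = c(low = 0, medium = 1, high = 2),
                                  denominator = c("all", "evaluable"),
                                  stage_points = c(I = 1, II = 1, III = 2, IV = 2),
                                  age_points = .default_age_points(),
                                  sex_nonfemale_points = 2,
                                  rarity_map = default_rarity_map(),
                                  derive_rarity = FALSE,
                                  rare_max_cases = 2,
                                  semirare_max_cases = 10,
                                  unlisted_pitfalls = c("error", "zero"),
                                  batch_size = 8,
                                  n_batches = 5,
                                  tie_break = "wsi_id") {
  denominator <- match.arg(denominator)
  unlisted_pitfalls <- match.arg(unlisted_pitfalls)
  tie_break <- match.arg(tie_break, "wsi_id")
  stopifnot(all(.density_bins %in% names(bin_weights)),
            all(c("lower", "upper", "points") %in% names(age_points)),
            batch_size >= 1, n_batches >= 1)
  structure(list(binning = binning,
                 bin_weights = bin_weights[.density_bins],
                 denominator = denominator,
                 stage_points = stage_points,
                 age_points = age_points,
                 sex_nonfemale_points = sex_nonfemale_points,
                 rarity_map = rarity_map,
                 derive_rarity = isTRUE(derive_rarity),
                 rare_max_cases = rare_max_cases,
                 semirare_max_cases = semirare_max_cases,
                 unlisted_pitfalls = unlisted_pitfalls,
                 batch_size = as.integer(batch_size),
                 n_batches = as.integer(n_batches),
                 tie_break = tie_break),
            class = "prioritization_config")
}

#' Read or write a prioritization configuration as JSON
#'
#' Only keys present in the file override the defaults, so a config file can
#' be sparse (e.g. just `{"batch_size": 10}`).
#'
#' @param path Path to a JSON file.
#' @param config A [prioritization_config()].
#' @return `read_prioritization_config()` returns a `prioritization_config`;
#'   `write_prioritization_config()` returns `path` invisibly.
#' @export
read_prioritization_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$binning))
    args$binning <- density_binning(raw$binning$low_max_pct,
                                    raw$binning$medium_max_pct)
  for (key in c("bin_weights", "denominator", "stage_points",
                "sex_nonfemale_points", "rarity_map", "derive_rarity",
                "rare_max_cases", "semirare_max_cases", "unlisted_pitfalls",
                "batch_size", "n_batches", "tie_break")) {
    if (!is.null(raw[[key]])) {
      val <- raw[[key]]
      args[[key]] <- if (is.list(val)) unlist(val) else val
    }
  }
  if (!is.null(raw$age_points)) {
    ap <- as.data.frame(raw$age_points)
    ap[] <- lapply(ap, as.numeric)
    # JSON has no Inf; an absent upper bound means "no upper bound"
    ap$upper[is.na(ap$upper)] <- Inf
    args$age_points <- ap
  }
  do.call(prioritization_config, args)
}

#' @rdname read_prioritization_config
#' @export
write_prioritization_config <- function(config, path) {
  out <- unclass(config)
  out$binning <- list(low_max_pct = config$binning$low_max_pct,
                      medium_max_pct = config$binning$medium_max_pct)
  jsonlite::write_json(listify_named(out), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# jsonlite writes named atomic vectors as nameless arrays; named point
# tables must survive the round trip, so turn them into objects.
listify_named <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, listify_named))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}
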