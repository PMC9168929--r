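#' Load the abiotic CH4 source compendium
#'
#' Reads the packaged catalogue of known abiotic methane sources and their
#' estimated global flux bounds (Tmol/y), spanning magmatic outgassing,
#' low-temperature water-rock and metamorphic reactions, and impact
#' delivery, for both the modern Earth and the Hadean/Archean. Each record
#' carries a provenance sentence naming its literature origin. Records whose
#' published yields are considered compromised by organic contamination
#' carry `quality = "contamination_suspect"` and hold no flux numbers.
#'
#' @param path Path to a compendium CSV; defaults to the file shipped with
#'   the package. Columns: `source_id`, `category` (one of `magmatic`,
#'   `water_rock_metamorphic`, `impact`), `era` (`modern` or
#'   `hadean_archean`), `flux_min_tmol_y`, `flux_max_tmol_y` (either may be
#'   empty), `quality`, `provenance`.
#' @return A data frame of class `abiotic_compendium`.
#' @examples
#' comp <- load_compendium()
#' max_abiotic_flux(comp)            # < 30 Tmol/y, the biogenic benchmark
#' max_abiotic_flux(comp, era = "modern")
#' @export
load_compendium <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "abiotic_ch4_sources.csv",
                        package = "methanesig", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("compendium file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(flux_min_tmol_y = "numeric",
                                        flux_max_tmol_y = "numeric"))
  if (nrow(rec) == 0) stop("compendium file is empty: ", path, call. = FALSE)
  .validate_compendium(rec)
  class(rec) <- c("abiotic_compendium", "data.frame")
  rec
}

.validate_compendium <- function(rec) {
  need <- c("source_id", "category", "era", "flux_min_tmol_y",
            "flux_max_tmol_y", "quality", "provenance")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols)) {
    stop("compendium is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    ok_cat <- r$category %in% c("magmatic", "water_rock_metamorphic", "impact")
    ok_era <- r$era %in% c("modern", "hadean_archean")
    ok_flux <- TRUE
    if (!is.na(r$flux_min_tmol_y) && r$flux_min_tmol_y < 0) ok_flux <- FALSE
    if (!is.na(r$flux_max_tmol_y) && r$flux_max_tmol_y < 0) ok_flux <- FALSE
    if (!is.na(r$flux_min_tmol_y) && !is.na(r$flux_max_tmol_y) &&
        r$flux_min_tmol_y > r$flux_max_tmol_y) ok_flux <- FALSE
    if (!ok_cat || !ok_era || !ok_flux) {
      stop("compendium record ", i, " ('", r$source_id, "') fails validation",
           call. = FALSE)
    }
  }
  invisible(rec)
}

#' Maximum abiotic CH4 flux over the compendium
#'
#' Largest `flux_max` among records matching an era filter. Records flagged
#' `contamination_suspect` are excluded unless explicitly requested,
#' mirroring the exclusion of laboratory yields that exceed the crustal
#' iron supply.
#'
#' @param records An `abiotic_compendium` (from [load_compendium()]).
#' @param era `"any"`, `"modern"` or `"hadean_archean"`.
#' @param include_suspect Include contamination-suspect records?
#' @return Maximum flux in Tmol/y.
#' @export
max_abiotic_flux <- function(records, era = c("any", "modern", "hadean_archean"),
                             include_suspect = FALSE) {
  stopifnot(inherits(records, "abiotic_compendium"))
  era <- match.arg(era)
  if (nrow(records) == 0) stop("empty record list", call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  if (era != "any") keep <- keep & records$era == era
  if (!include_suspect) keep <- keep & records$quality != "contamination_suspect"
  keep <- keep & !is.na(records$flux_max_tmol_y)
  if (!any(keep)) stop("no records match era '", era, "'", call. = FALSE)
  max(records$flux_max_tmol_y[keep])
}
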