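# Survey ingestion: raw point-count tables -> per-sample biomass rows for
# the indicator (titmouse) and target (other forest birds) groups.

#' Read a point-count table
#'
#' Reads a delimited text file of species counts, one row per
#' site/point/year/(period)/species.  Column names are mapped through
#' `dialect`, so files from different monitoring schemes can be ingested
#' without renaming.  Duplicate key rows (same site, point, year, period and
#' species) are summed with a warning: field sheets often split one species
#' over several lines.
#'
#' @param path delimited text file with a header row.
#' @param dialect named list mapping the canonical column names `site_id`,
#'   `point_id`, `year`, `species_code`, `count` (and optionally `period`,
#'   `habitat_code`) to the file's column names; entries equal to their own
#'   name may be omitted.
#' @param mode `"pair_counts"` (each count is a breeding pair, one annual
#'   period) or `"individual_counts"`.
#' @param sep field separator; `""` (default) auto-detects comma vs tab from
#'   the header line.
#' @return a data.frame of class `point_counts` with canonical columns
#'   `site_id`, `point_id`, `year`, `period`, `species_code`, `count`,
#'   `habitat_code` and attribute `mode`.
#' @export
readPointCounts <- function(path, dialect = list(),
                            mode = c("individual_counts", "pair_counts"),
                            sep = "") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (sep == "") {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_id", "point_id", "year", "species_code", "count")
  opt <- c("period", "habitat_code")
  cols <- stats::setNames(as.list(c(need, opt)), c(need, opt))
  cols[names(dialect)] <- dialect
  miss <- need[!unlist(cols[need]) %in% names(raw)]
  if (length(miss)) {
    stop("column mapping does not cover required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(site_id = as.character(raw[[cols$site_id]]),
                   point_id = as.character(raw[[cols$point_id]]),
                   year = as.integer(raw[[cols$year]]),
                   period = if (cols$period %in% names(raw)) {
                     as.integer(raw[[cols$period]])
                   } else 1L,
                   species_code = as.character(raw[[cols$species_code]]),
                   count = raw[[cols$count]],
                   habitat_code = if (cols$habitat_code %in% names(raw)) {
                     as.character(raw[[cols$habitat_code]])
                   } else NA_character_,
                   stringsAsFactors = FALSE)
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    stop("non-integer or negative count in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  df$count <- as.integer(cnt)
  if (mode == "pair_counts" && any(df$period != 1L)) {
    stop("pair_counts mode implies a single annual period", call. = FALSE)
  }
  key <- paste(df$site_id, df$point_id, df$year, df$period, df$species_code,
               sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate key row(s) in ", basename(path),
            "; counts summed", call. = FALSE)
    agg <- rowsum(df$count, key)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  }
  rownames(df) <- NULL
  structure(df, mode = mode, class = c("point_counts", "data.frame"))
}

countMode <- function(records) {
  m <- attr(records, "mode")
  if (is.null(m)) "individual_counts" else m
}

#' Double pair counts into individual counts
#'
#' Surveys whose census unit is a breeding pair record half the individuals;
#' every count is multiplied by two and the record set switches to
#' individual-count mode.  Applying it to data already in individual-count
#' mode is an error (the doubling must happen exactly once).
#'
#' @param records a `point_counts` data.frame in pair-count mode.
#' @return the records with doubled counts, in individual-count mode.
#' @export
pairsToIndividuals <- function(records) {
  if (countMode(records) != "pair_counts") {
    stop("records are already individual counts; refusing to double again",
         call. = FALSE)
  }
  records$count <- records$count * 2L
  attr(records, "mode") <- "individual_counts"
  records
}

#' Sum counts over breeding periods
#'
#' Schemes with two within-season visits are collapsed to one annual record
#' per species by summing the period counts within each
#' (site, point, year, species); the resulting period is 1.
#'
#' @param records a `point_counts` data.frame in individual-count mode.
#' @return records with one row per (site, point, year, species).
#' @export
mergeBreedingPeriods <- function(records) {
  if (countMode(records) != "individual_counts") {
    stop("sum periods after converting pairs to individuals", call. = FALSE)
  }
  key <- paste(records$site_id, records$point_id, records$year,
               records$species_code, sep = "\r")
  agg <- rowsum(records$count, key)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  out$period <- 1L
  rownames(out) <- NULL
  attr(out, "mode") <- "individual_counts"
  out
}

#' Read a species trait table
#'
#' @param path delimited text with columns `species_code`, `body_mass` (g),
#'   `is_titmouse`, `is_excluded_guild`, `is_forest` (logical or 0/1).
#' @param sep field separator, auto-detected when `""`.
#' @return data.frame of traits.
#' @export
readSpeciesTraits <- function(path, sep = "") {
  if (sep == "") {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  tr <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("species_code", "body_mass", "is_titmouse", "is_excluded_guild",
            "is_forest")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("is_titmouse", "is_excluded_guild", "is_forest")) {
    tr[[f]] <- as.logical(tr[[f]])
  }
  if (any(tr$body_mass <= 0)) stop("non-positive body mass", call. = FALSE)
  if (any(tr$is_titmouse & tr$is_excluded_guild)) {
    stop("a species cannot be both titmouse and excluded guild",
         call. = FALSE)
  }
  tr
}

#' Apply guild and habitat-group filters
#'
#' Removes species surveyed unreliably by point counts (raptors, grouse,
#' waders, waterfowl; flagged `is_excluded_guild`) and all non-forest
#' species.  Every species code in the records must appear in the trait
#' table.
#'
#' @param records a `point_counts` data.frame.
#' @param traits a trait table as from [readSpeciesTraits()].
#' @return the filtered records.
#' @export
applyGuildFilters <- function(records, traits) {
  idx <- match(records$species_code, traits$species_code)
  if (anyNA(idx)) {
    stop("species missing from trait table: ",
         paste(unique(records$species_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- !traits$is_excluded_guild[idx] & traits$is_forest[idx]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- countMode(records)
  out
}

#' Build per-sample biomass rows
#'
#' Aggregates filtered individual counts into one row per point and year:
#' `tit` is the summed biomass (count times body mass, g) of the titmouse
#' species, `b` the summed biomass of all other forest species.  When a
#' control-group species set is given, those species are removed from `b`
#' and summed into `control` instead.  Locations (planar km) are joined per
#' point, falling back to the site centroid when a point has no coordinates.
#'
#' @param records filtered `point_counts` in individual-count mode.
#' @param traits trait table covering all species present.
#' @param locations data.frame with `site_id`, `point_id`, `x`, `y` (km);
#'   rows with missing `point_id` give site centroids.
#' @param area sampled area per point count (km^2), constant across samples.
#' @param control_species optional character vector of control-group species
#'   codes; must not contain titmice.
#' @return data.frame with columns `site_id`, `point_id`, `year`, `x`, `y`,
#'   `b`, `tit`, `control`, `area`, `habitat_code` -- including point-years
#'   where no birds at all were recorded are *not* present (absence rows
#'   cannot be distinguished from unsurveyed point-years in count files).
#' @export
buildSamples <- function(records, traits, locations, area = 0.031,
                         control_species = NULL) {
  if (countMode(records) != "individual_counts") {
    stop("convert pairs to individuals before building samples",
         call. = FALSE)
  }
  idx <- match(records$species_code, traits$species_code)
  if (anyNA(idx)) {
    stop("species missing from trait table: ",
         paste(unique(records$species_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(control_species)) {
    ct <- traits$is_titmouse[match(control_species, traits$species_code)]
    if (any(is.na(ct))) {
      stop("control species not in trait table: ",
           paste(control_species[is.na(ct)], collapse = ", "), call. = FALSE)
    }
    if (any(ct)) {
      stop("control group must not contain titmouse species", call. = FALSE)
    }
  }
  biomass <- records$count * traits$body_mass[idx]
  group <- ifelse(traits$is_titmouse[idx], "tit",
                  ifelse(records$species_code %in% control_species,
                         "control", "b"))
  key <- paste(records$site_id, records$point_id, records$year, sep = "\r")
  ag <- function(g) {
    s <- rowsum(ifelse(group == g, biomass, 0), key)
    s[, 1L]
  }
  first <- !duplicated(key)
  out <- data.frame(site_id = records$site_id[first],
                    point_id = records$point_id[first],
                    year = records$year[first],
                    stringsAsFactors = FALSE)
  k1 <- key[first]
  out$b <- ag("b")[k1]
  out$tit <- ag("tit")[k1]
  out$control <- if (length(control_species)) ag("control")[k1] else 0
  out$area <- area
  out$habitat_code <- records$habitat_code[first]
  # join locations: exact point first, then site centroid
  pk <- paste(locations$site_id, locations$point_id, sep = "\r")
  m <- match(paste(out$site_id, out$point_id, sep = "\r"), pk)
  out$x <- NA_real_
  out$y <- NA_real_
  if (anyNA(m)) {
    cen_x <- tapply(locations$x, locations$site_id, mean)
    cen_y <- tapply(locations$y, locations$site_id, mean)
    miss <- is.na(m)
    out$x[!miss] <- locations$x[m[!miss]]
    out$y[!miss] <- locations$y[m[!miss]]
    out$x[miss] <- cen_x[out$site_id[miss]]
    out$y[miss] <- cen_y[out$site_id[miss]]
    if (anyNA(out$x)) {
      stop("no location for point(s): ",
           paste(utils::head(unique(
             out$point_id[is.na(out$x)]), 5L), collapse = ", "),
           call. = FALSE)
    }
  } else {
    out$x <- locations$x[m]
    out$y <- locations$y[m]
  }
  rownames(out) <- NULL
  out[order(out$site_id, out$point_id, out$year),
      c("site_id", "point_id", "year", "x", "y", "b", "tit", "control",
        "area", "habitat_code")]
}
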