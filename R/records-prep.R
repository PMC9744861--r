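# From raw opportunistic records to per-species detection histories.
#
# The observation replicate is the visit: all records made by one
# observer or project on one day in one square.  Filters follow the
# analysis protocol: adult records only, squares informative about
# change (visited in >1 year), species recorded in enough years, and
# per-species visit eligibility (project taxonomic coverage, day-of-year
# quantile window, zones with at least one record).

#' Filter raw records
#'
#' Applies the record-level filters: (1) non-adult stages removed;
#' (2) records outside the study range removed, where each group's range
#' may start earlier by a warm-up period (warm-up years are kept for
#' model fitting and trimmed from derived series later); (3) squares
#' whose records all fall within a single year removed (no information
#' on change), assessed separately per group dataset.
#'
#' @param records RecordTable (columns `species_id`, `group`,
#'   `square_id`, `year`, `doy`, `observer_id`, `project_id`,
#'   `life_stage`).
#' @param start_year,end_year focal study range.
#' @param warmup_years named vector of warm-up years per group
#'   (default 0 for all groups present).
#' @param quiet suppress per-filter row-count messages.
#' @return the filtered RecordTable.
#' @export
filter_records <- function(records, start_year, end_year,
                           warmup_years = NULL, quiet = FALSE) {
  n0 <- nrow(records)
  if (is.null(warmup_years)) {
    warmup_years <- stats::setNames(rep(0L, length(unique(records$group))),
                                    unique(records$group))
  }
  keep <- records$life_stage == "adult"
  n_stage <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stopf("no records left after the non-adult filter")

  wu <- warmup_years[records$group]
  wu[is.na(wu)] <- 0L
  keep <- records$year >= (start_year - wu) & records$year <= end_year
  n_range <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stopf("no records left after the study-range filter")

  # squares informative about change, per group dataset
  key <- paste(records$group, records$square_id)
  nyr <- tapply(records$year, key, function(y) length(unique(y)))
  keep <- nyr[key] > 1L
  n_single <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) stopf("no records left after the single-year-square filter")

  if (!quiet) {
    message(sprintf(
      "filter_records: %d in; removed %d non-adult, %d out-of-range, %d single-year-square; %d out",
      n0, n_stage, n_range, n_single, nrow(records)))
  }
  rownames(records) <- NULL
  records
}

#' Build the visit table from records
#'
#' Groups records into visits (one observer or project, one day, one
#' square), counts distinct species per visit, and assigns the
#' list-length class (1; 2-3; >3).  Rows lacking both an observer and a
#' project key cannot be attributed to a visit and are dropped with a
#' warning.
#'
#' @param records RecordTable.
#' @return list with `visits` (VisitTable: `visit_id`, `square_id`,
#'   `year`, `doy`, `group`, `obs_key`, `observer_id`, `project_id`,
#'   `source_hint`, `n_species`, `list_class`) and `visit_species`
#'   (long map `visit_id` x `species_id`).
#' @export
build_visits <- function(records) {
  no_key <- (is.na(records$observer_id) | records$observer_id == "") &
    (is.na(records$project_id) | records$project_id == "")
  if (any(no_key)) {
    warnf("%d record(s) without observer or project key dropped", sum(no_key))
    records <- records[!no_key, , drop = FALSE]
  }
  obs_key <- ifelse(!is.na(records$project_id) & records$project_id != "",
                    records$project_id, records$observer_id)
  key <- paste(records$group, obs_key, records$year, records$doy,
               records$square_id, sep = "\r")
  uk <- !duplicated(key)
  visits <- data.frame(
    visit_id = NA_character_,
    square_id = records$square_id[uk], year = records$year[uk],
    doy = records$doy[uk], group = records$group[uk],
    obs_key = obs_key[uk], observer_id = records$observer_id[uk],
    project_id = records$project_id[uk], source_hint = records$source_hint[uk])
  ord <- order(visits$group, visits$year, visits$doy, visits$square_id, visits$obs_key)
  visits <- visits[ord, , drop = FALSE]
  visits$visit_id <- sprintf("v%06d", seq_len(nrow(visits)))
  vkey <- paste(visits$group, visits$obs_key, visits$year, visits$doy,
                visits$square_id, sep = "\r")
  vid <- visits$visit_id[match(key, vkey)]
  vs <- unique(data.frame(visit_id = vid, species_id = records$species_id))
  nsp <- table(vs$visit_id)
  visits$n_species <- as.integer(nsp[visits$visit_id])
  visits$list_class <- list_length_class(visits$n_species)
  rownames(visits) <- NULL
  list(visits = visits, visit_species = vs)
}

#' List-length class of a visit
#'
#' @param n number of species recorded during the visit.
#' @return factor with levels `"1"`, `"2-3"`, `">3"`.
#' @export
list_length_class <- function(n) {
  factor(ifelse(n <= 1, "1", ifelse(n <= 3, "2-3", ">3")),
         levels = c("1", "2-3", ">3"))
}

#' Select species with sufficient temporal coverage
#'
#' A species is analysed if it was recorded (in any square) in at least
#' `min_year_fraction` of the analysed years.
#'
#' @param records RecordTable (after filtering).
#' @param analysed_years vector of analysed calendar years (e.g.
#'   1980:2020; warm-up years do not count).
#' @param min_year_fraction inclusion threshold (default 0.25).
#' @return character vector of retained species ids.
#' @export
select_species <- function(records, analysed_years, min_year_fraction = 0.25) {
  r <- records[records$year %in% analysed_years, , drop = FALSE]
  nyr <- tapply(r$year, r$species_id, function(y) length(unique(y)))
  keep <- nyr / length(analysed_years) >= min_year_fraction
  sort(names(nyr)[keep])
}

#' Classify observers as expert naturalists
#'
#' An expert naturalist is an observer (i) in the upper 2.5% quantile of
#' all observers arranged by their total number of records and (ii) with
#' at least one visit in the upper 2.5% quantile of all visits arranged
#' by the number of records (an exceptionally long species list).
#' Quantiles are empirical (type 7) and ties at the threshold are kept
#' inclusive.
#'
#' @param visits VisitTable from [build_visits()].
#' @param records the RecordTable the visits were built from.
#' @return data.frame `observer_id`, `n_records`, `expert`.
#' @export
classify_observers <- function(visits, records) {
  per_obs <- tapply(rep(1L, nrow(records)), records$observer_id, sum)
  obs_thr <- stats::quantile(per_obs, 0.975, type = 7, names = FALSE)
  top_obs <- names(per_obs)[per_obs >= obs_thr]
  list_thr <- stats::quantile(visits$n_species, 0.975, type = 7, names = FALSE)
  pv <- visits[!is.na(visits$observer_id), , drop = FALSE]
  long_by <- tapply(pv$n_species, pv$observer_id, max)
  has_long <- names(long_by)[long_by >= list_thr]
  data.frame(observer_id = names(per_obs),
             n_records = as.integer(per_obs),
             expert = names(per_obs) %in% intersect(top_obs, has_long),
             row.names = NULL)
}

#' Five-level source class of a visit
#'
#' Reference level is a plain naturalist observation; the other levels
#' are expert naturalist, unspecified project, project targeted at the
#' focal species, and Red-List inventory.  The expert level applies to
#' person-sourced visits by classified expert observers; the targeted
#' level is species-specific and resolved in
#' [build_detection_histories()].
#'
#' @return character vector of the level names, in model order.
#' @export
source_levels <- function() {
  c("naturalist", "expert", "project", "targeted_project", "redlist")
}

#' Build the detection history of one species
#'
#' Restricts the visit table to eligible visits for the focal species:
#' (a) visits from projects whose taxonomic coverage excludes the
#' species are dropped; (b) visits outside the empirical 5%-95%
#' day-of-year window of the species' records are dropped (pooled over
#' years, inclusive at the boundaries); (c) visits from bioclimatic
#' zones without a single record of the species are dropped.  For the
#' remaining visits, the detection indicator and the detection
#' covariates (scaled day of year, list-length class, five-level source
#' class, zone, year) are assembled.
#'
#' @param species_id focal species.
#' @param visits VisitTable.
#' @param visit_species long visit x species map from [build_visits()].
#' @param records RecordTable (for the day-of-year quantiles and zone
#'   coverage).
#' @param frame StudyFrame (square -> zone mapping).
#' @param experts output of [classify_observers()] (NULL = no experts).
#' @param projects project metadata with columns `project_id`, `group`,
#'   `target_species` (NA = whole group); NULL means every project
#'   covers every species.
#' @param doy_quantiles day-of-year window probabilities (default
#'   c(0.05, 0.95)).
#' @return DetectionHistory data.frame: `visit_id`, `square_id`, `zone`,
#'   `year`, `y`, `yday_s`, `list_class`, `source_class`; attributes
#'   `species_id`, `doy_window`, `doy_scaling`.  NULL (with a warning)
#'   if no eligible visit remains.
#' @export
build_detection_histories <- function(species_id, visits, visit_species,
                                      records, frame, experts = NULL,
                                      projects = NULL,
                                      doy_quantiles = c(0.05, 0.95)) {
  recs <- records[records$species_id == species_id, , drop = FALSE]
  if (!nrow(recs)) {
    warnf("species %s has no records; excluded", species_id)
    return(NULL)
  }
  grp <- recs$group[1]
  v <- visits[visits$group == grp, , drop = FALSE]

  # (a) project taxonomic coverage
  if (!is.null(projects)) {
    pr <- projects[match(v$project_id, projects$project_id), ]
    covered <- is.na(v$project_id) |
      (pr$group == grp & (is.na(pr$target_species) | pr$target_species == species_id))
    covered[is.na(covered)] <- TRUE
    v <- v[covered, , drop = FALSE]
  }

  # (b) day-of-year window from this species' records, pooled years
  win <- stats::quantile(recs$doy, doy_quantiles, type = 7, names = FALSE)
  v <- v[v$doy >= win[1] & v$doy <= win[2], , drop = FALSE]

  # (c) zones with at least one record of the species
  zone_of <- stats::setNames(frame$zone, frame$square_id)
  occ_zones <- unique(zone_of[recs$square_id])
  v$zone <- zone_of[v$square_id]
  v <- v[v$zone %in% occ_zones, , drop = FALSE]
  if (!nrow(v)) {
    warnf("species %s has no eligible visits; excluded", species_id)
    return(NULL)
  }

  det_vids <- visit_species$visit_id[visit_species$species_id == species_id]
  y <- as.integer(v$visit_id %in% det_vids)

  expert_ids <- if (is.null(experts)) character() else
    experts$observer_id[experts$expert]
  src <- rep("naturalist", nrow(v))
  src[v$source_hint == "project"] <- "project"
  src[v$source_hint == "redlist"] <- "redlist"
  if (!is.null(projects)) {
    pr <- projects[match(v$project_id, projects$project_id), ]
    src[!is.na(pr$target_species) & pr$target_species == species_id] <- "targeted_project"
  } else {
    src[v$source_hint == "targeted_project"] <- "targeted_project"
  }
  person <- is.na(v$project_id) | v$project_id == ""
  src[person & v$observer_id %in% expert_ids] <- "expert"

  mu <- mean(v$doy); sdv <- stats::sd(v$doy)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  out <- data.frame(visit_id = v$visit_id, square_id = v$square_id,
                    zone = v$zone, year = v$year,
                    y = y, yday_s = (v$doy - mu) / sdv,
                    list_class = v$list_class,
                    source_class = factor(src, levels = source_levels()))
  attr(out, "species_id") <- species_id
  attr(out, "doy_window") <- win
  attr(out, "doy_scaling") <- c(center = mu, scale = sdv)
  out
}
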