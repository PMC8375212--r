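#' Feature dictionary
#'
#' The default vocabulary of streetscape features coders record from
#' imagery: line features are stretches of infrastructure along the road
#' (footpaths, cycleways, on-street parking), point features are discrete
#' installations or destinations. Speed bumps and traffic-calming signs
#' fold into the single `traffic_calming` code, distinguished by a free
#' text subtype note.
#'
#' @param extra optional data.frame of additional codes with the same
#'   columns (`code`, `label`, `kind`, `category`), e.g. separate bus
#'   shelter / bus sign codes when a council supplies them separately.
#' @return data.frame with columns `code`, `label`, `kind` (`point` or
#'   `line`) and `category`.
#' @export
feature_dictionary <- function(extra = NULL) {
  d <- data.frame(
    code = c("footpath", "cycleway", "public_transport",
             "pedestrian_crossing", "on_street_parking",
             "traffic_calming", "park_playground", "food_outlet"),
    label = c("Footpath", "Cycleway", "Public transport stop",
              "Pedestrian crossing", "On-street parking",
              "Traffic calming feature", "Park / playground / PA facility",
              "Food outlet"),
    kind = c("line", "line", "point", "point", "line", "point", "point",
             "point"),
    category = c("physical_activity", "physical_activity", "traffic",
                 "traffic", "traffic", "traffic", "physical_activity",
                 "food"))
  if (!is.null(extra)) {
    stopifnot(all(c("code", "label", "kind", "category") %in% names(extra)))
    d <- rbind(d, extra[c("code", "label", "kind", "category")])
  }
  if (anyDuplicated(d$code))
    stop_streetaudit("duplicate feature codes in dictionary",
                     "streetaudit_bad_dictionary")
  d
}

#' Food-outlet subtype vocabulary
#'
#' Place tags accepted as free-text-validated subtypes of `food_outlet`.
#' @return character vector.
#' @export
outlet_subtypes <- function() {
  c("bakery", "cafe", "convenience store", "gas station", "liquor store",
    "meal takeaway", "park", "restaurant", "shopping mall", "supermarket")
}

#' Read / write a feature dictionary as YAML
#' @param dictionary data.frame from [feature_dictionary()].
#' @param path file path.
#' @export
write_dictionary_yaml <- function(dictionary, path) {
  entries <- lapply(seq_len(nrow(dictionary)), function(i)
    as.list(dictionary[i, c("label", "kind", "category")]))
  names(entries) <- dictionary$code
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_dictionary_yaml
#' @export
read_dictionary_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  d <- do.call(rbind, lapply(names(entries), function(code)
    data.frame(code = code, label = entries[[code]]$label,
               kind = entries[[code]]$kind,
               category = entries[[code]]$category)))
  rownames(d) <- NULL
  d
}

#' Ingest coder checklist batches
#'
#' Reads one CSV per coder batch (columns `coordinate_id`, `feature_code`,
#' `subtype`, `coder`, `batch`), validates rows against the feature
#' dictionary and the sampled-coordinate manifest, drops exact duplicates,
#' and merges into a single observation table sorted by (coordinate id,
#' feature code). Validation problems are reported, not fatal; an
#' unreadable file is an error naming the file.
#'
#' @param paths character vector of CSV paths, or a list of data.frames.
#' @param dictionary data.frame from [feature_dictionary()].
#' @param valid_ids character vector of known coordinate ids (sampled
#'   points and council audit coordinates).
#' @return list with `observations` (the merged table) and `issues`
#'   (data.frame: `source`, `row`, `reason`).
#' @export
ingest_batches <- function(paths, dictionary, valid_ids) {
  required <- c("coordinate_id", "feature_code")
  tabs <- list()
  issues <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    src <- if (is.character(p)) p else sprintf("batch%d", i)
    tab <- if (is.character(p)) {
      t <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                    error = function(e) e)
      if (inherits(t, "error"))
        stop_streetaudit(sprintf("cannot read batch file '%s': %s", p,
                                 conditionMessage(t)),
                         "streetaudit_bad_batch")
      t
    } else as.data.frame(p)
    if (!all(required %in% names(tab)))
      stop_streetaudit(sprintf("batch '%s' lacks columns %s", src,
                               paste(setdiff(required, names(tab)),
                                     collapse = ", ")),
                       "streetaudit_bad_batch")
    for (col in c("subtype", "coder", "batch")) {
      if (is.null(tab[[col]])) tab[[col]] <- rep("", nrow(tab))
      tab[[col]] <- as.character(tab[[col]])
      tab[[col]][is.na(tab[[col]])] <- ""
    }
    tab <- tab[c("coordinate_id", "feature_code", "subtype", "coder", "batch")]
    bad_code <- !(tab$feature_code %in% dictionary$code)
    bad_id <- !(tab$coordinate_id %in% valid_ids)
    if (any(bad_code))
      issues[[length(issues) + 1L]] <-
        data.frame(source = src, row = which(bad_code),
                   reason = paste0("unknown feature code '",
                                   tab$feature_code[bad_code], "'"))
    if (any(bad_id))
      issues[[length(issues) + 1L]] <-
        data.frame(source = src, row = which(bad_id),
                   reason = paste0("unknown coordinate id '",
                                   tab$coordinate_id[bad_id], "'"))
    tabs[[length(tabs) + 1L]] <- tab[!bad_code & !bad_id, , drop = FALSE]
  }
  merged <- do.call(rbind, tabs)
  dup <- duplicated(merged)
  if (any(dup)) {
    issues[[length(issues) + 1L]] <-
      data.frame(source = "merged", row = which(dup),
                 reason = "exact duplicate row")
    merged <- merged[!dup, , drop = FALSE]
  }
  merged <- merged[order(merged$coordinate_id, merged$feature_code), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(source = character(0), row = integer(0),
               reason = character(0))
  rownames(issues) <- NULL
  list(observations = merged, issues = issues)
}

#' Draw a reproducible QA review subset
#'
#' Samples `round_half_up(fraction * n)` image ids without replacement for
#' independent re-review, deterministically for a given seed.
#'
#' @param ids character vector of image or coordinate ids.
#' @param fraction fraction to review (default 0.10).
#' @param seed integer RNG seed.
#' @return sorted character vector of selected ids.
#' @export
qa_sample <- function(ids, fraction = 0.10, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round_half_up(fraction * length(ids))
  if (k == 0) return(character(0))
  sort(with_seed(seed, sample(ids, size = k, replace = FALSE)))
}
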