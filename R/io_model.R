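#' @title Domain tables: roster, interactions, census, outcomes
#' @description CSV readers/writers and validation shared by every stage of the
#'   pipeline. All tables are plain data frames with a light S3 class tag so
#'   downstream functions can check what they received.
#' @name io_model
NULL

SEXES <- c("male", "female", "juvenile")

#' Treatment arm codes of the shell-manipulation experiment
#'
#' Three controls (C1 untouched; C2 broken shells replaced with other broken
#' shells; C3 broken shells added), two replacing arms (R2/R4: two or four
#' broken shells replaced with intact ones), two adding arms (A2/A4: two or
#' four intact shells added) and two combination arms (AR2/AR4: both).
#' @export
TREATMENTS <- c("C1", "C2", "C3", "R2", "R4", "A2", "A4", "AR2", "AR4")

#' Read an individual roster
#'
#' The roster lists every individual of the Part I study communities: its id,
#' sex, social group, community, and whether it is the focal male whose shell
#' nest was augmented. Each manipulated community must contain exactly one
#' manipulated individual, and that individual must be an adult male.
#'
#' @param path CSV file with header columns `id, sex, group, community,
#'   manipulated`.
#' @return A data frame of class `roster` with columns `id`, `sex`
#'   (male/female/juvenile), `group_id`, `community_id`, `manipulated`.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "group", "community", "manipulated")
  if (!all(need %in% names(df)))
    stop("roster is missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(
    id = as.character(df$id),
    sex = as.character(df$sex),
    group_id = as.character(df$group),
    community_id = as.character(df$community),
    manipulated = as.logical(df$manipulated),
    stringsAsFactors = FALSE
  )
  validate_roster(out)
}

#' @rdname read_roster
#' @param roster a roster-shaped data frame to validate.
#' @export
validate_roster <- function(roster) {
  bad <- setdiff(unique(roster$sex), SEXES)
  if (length(bad)) stop("unknown sex value(s): ", paste(bad, collapse = ", "))
  if (any(is.na(roster$manipulated))) stop("roster 'manipulated' must be TRUE/FALSE")
  dup <- stats::aggregate(id ~ community_id, roster, function(x) anyDuplicated(x) > 0)
  if (any(dup$id)) stop("duplicated ids within community: ",
                        paste(dup$community_id[dup$id], collapse = ", "))
  man <- roster[roster$manipulated, , drop = FALSE]
  if (nrow(man)) {
    per <- table(man$community_id)
    if (any(per != 1))
      stop("each manipulated community must have exactly one manipulated individual")
    if (any(man$sex != "male"))
      stop("manipulated individuals must be adult males")
  }
  class(roster) <- c("roster", "data.frame")
  roster
}

#' Read dyadic interaction records
#'
#' One row per observed directed interaction (or per tally of identical
#' interactions): which individual initiated, which received, on what day, of
#' what behavioural class, and how many times. Rows with identical keys are
#' aggregated by summing their counts. Self-loops and ids absent from the
#' roster are rejected. Juveniles do not take part in the scored adult
#' interactions, so rows involving a juvenile are dropped on load (with a
#' warning).
#'
#' @param path CSV file with header columns `community, day, initiator,
#'   receiver, class, count`.
#' @param roster roster as returned by [read_roster()].
#' @return Data frame of class `interactions` with columns `community_id`,
#'   `day`, `initiator_id`, `receiver_id`, `iclass`, `count`.
#' @export
read_interactions <- function(path, roster) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("community", "day", "initiator", "receiver", "class", "count")
  if (!all(need %in% names(raw)))
    stop("interaction file is missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0) {
    out <- data.frame(community_id = character(), day = integer(),
                      initiator_id = character(), receiver_id = character(),
                      iclass = character(), count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("interactions", "data.frame")
    return(out)
  }
  day <- suppressWarnings(as.integer(raw$day))
  count <- suppressWarnings(as.integer(raw$count))
  bad <- which(is.na(day) | is.na(count) | count < 0 | day < 1)
  if (length(bad))
    stop("malformed interaction row at line ", bad[1] + 1L,
         " (day and count must be positive integers)")
  df <- data.frame(community_id = raw$community, day = day,
                   initiator_id = raw$initiator, receiver_id = raw$receiver,
                   iclass = raw$class, count = count, stringsAsFactors = FALSE)
  validate_interactions(df, roster)
}

#' @rdname read_interactions
#' @param records interaction-shaped data frame to validate/aggregate.
#' @export
validate_interactions <- function(records, roster) {
  bad <- setdiff(unique(records$iclass), c("affiliative", "aggressive"))
  if (length(bad)) stop("unknown interaction class: ", paste(bad, collapse = ", "))
  loops <- which(records$initiator_id == records$receiver_id)
  if (length(loops))
    stop("self-loop interaction (initiator == receiver) at row ", loops[1])
  known <- paste(roster$community_id, roster$id)
  miss <- !(paste(records$community_id, records$initiator_id) %in% known) |
          !(paste(records$community_id, records$receiver_id) %in% known)
  if (any(miss))
    stop("interaction row ", which(miss)[1],
         " references an id not in the roster for its community")
  juv <- roster$id[roster$sex == "juvenile"]
  isjuv <- records$initiator_id %in% juv | records$receiver_id %in% juv
  if (any(isjuv)) {
    warning(sum(isjuv), " interaction row(s) involving juveniles dropped")
    records <- records[!isjuv, , drop = FALSE]
  }
  # aggregate duplicate (community, day, dyad, class) keys
  if (nrow(records)) {
    agg <- stats::aggregate(
      count ~ community_id + day + initiator_id + receiver_id + iclass,
      data = records, FUN = sum)
    agg <- agg[order(agg$community_id, agg$day, agg$initiator_id,
                     agg$receiver_id, agg$iclass), , drop = FALSE]
    rownames(agg) <- NULL
    records <- agg
  }
  class(records) <- c("interactions", "data.frame")
  records
}

#' Write interaction records to CSV
#' @param records interactions table.
#' @param path output CSV path.
#' @export
write_interactions <- function(records, path) {
  out <- data.frame(community = records$community_id, day = records$day,
                    initiator = records$initiator_id,
                    receiver = records$receiver_id,
                    class = records$iclass, count = records$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  out <- data.frame(id = roster$id, sex = roster$sex, group = roster$group_id,
                    community = roster$community_id,
                    manipulated = roster$manipulated)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read Part II census tables
#'
#' Five census rows per experimental group: composition counts, the treatment
#' arm, whether the territory had been lost to a heterospecific usurper, and
#' whether a heterospecific was present. Territory loss is an absorbing state:
#' once `lost` is TRUE it must stay TRUE for later observations (violations
#' are an error). Groups with a number of observations other than five are
#' kept but flagged `excluded = TRUE` with a warning.
#'
#' @param path CSV with header columns `group, treatment, obs, males, females,
#'   juveniles, lost, heterospecific`.
#' @return Data frame of class `census` with columns `group_id`, `treatment`,
#'   `obs_index`, `n_males`, `n_females`, `n_juveniles`, `territory_lost`,
#'   `heterospecific_present`, `excluded`.
#' @export
read_census <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "treatment", "obs", "males", "females", "juveniles",
            "lost", "heterospecific")
  if (!all(need %in% names(df)))
    stop("census file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(
    group_id = as.character(df$group), treatment = as.character(df$treatment),
    obs_index = as.integer(df$obs), n_males = as.integer(df$males),
    n_females = as.integer(df$females), n_juveniles = as.integer(df$juveniles),
    territory_lost = as.logical(df$lost),
    heterospecific_present = as.logical(df$heterospecific),
    stringsAsFactors = FALSE)
  validate_census(out)
}

#' @rdname read_census
#' @param census census-shaped data frame to validate.
#' @export
validate_census <- function(census) {
  bad <- setdiff(unique(census$treatment), TREATMENTS)
  if (length(bad)) stop("unknown treatment code(s): ", paste(bad, collapse = ", "))
  if (any(census$n_males < 0 | census$n_females < 0 | census$n_juveniles < 0,
          na.rm = TRUE))
    stop("negative census counts")
  census <- census[order(census$group_id, census$obs_index), , drop = FALSE]
  rownames(census) <- NULL
  excl <- character()
  for (g in unique(census$group_id)) {
    rows <- census[census$group_id == g, , drop = FALSE]
    if (is.unsorted(rows$territory_lost))  # FALSE < TRUE: loss must be absorbing
      stop("territory_lost is not monotone for group ", g)
    if (nrow(rows) != 5L) excl <- c(excl, g)
  }
  if (length(excl))
    warning("group(s) without exactly 5 observations flagged excluded: ",
            paste(excl, collapse = ", "))
  census$excluded <- census$group_id %in% excl
  class(census) <- c("census", "data.frame")
  census
}

#' @rdname read_census
#' @export
write_census <- function(census, path) {
  out <- data.frame(group = census$group_id, treatment = census$treatment,
                    obs = census$obs_index, males = census$n_males,
                    females = census$n_females, juveniles = census$n_juveniles,
                    lost = census$territory_lost,
                    heterospecific = census$heterospecific_present)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a census table to per-group treatment outcomes
#'
#' One row per group: its arm, whether the territory was ever lost, and the
#' change in the number of males/females/juveniles between the final and the
#' first census. Positive deltas mean recruitment (last minus first). Groups
#' that lost their territory carry `NA` deltas and are excluded from the
#' membership-change models; groups flagged `excluded` on load are dropped.
#'
#' @param census validated census table from [read_census()].
#' @return Data frame of class `outcomes` with columns `group_id`, `treatment`,
#'   `lost`, `delta_males`, `delta_females`, `delta_juveniles`.
#' @export
to_outcomes <- function(census) {
  stopifnot(inherits(census, "census") || all(c("group_id", "obs_index") %in% names(census)))
  if (!is.null(census$excluded)) census <- census[!census$excluded, , drop = FALSE]
  groups <- unique(census$group_id)
  res <- lapply(groups, function(g) {
    rows <- census[census$group_id == g, , drop = FALSE]
    rows <- rows[order(rows$obs_index), , drop = FALSE]
    lost <- any(rows$territory_lost)
    n <- nrow(rows)
    d <- function(col) if (lost) NA_integer_ else rows[[col]][n] - rows[[col]][1]
    data.frame(group_id = g, treatment = rows$treatment[1], lost = lost,
               delta_males = d("n_males"), delta_females = d("n_females"),
               delta_juveniles = d("n_juveniles"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("outcomes", "data.frame")
  out
}

#' Validate a directory of pipeline input CSVs
#'
#' Convenience check used by the command-line wrapper: reads
#' `roster.csv`, `interactions.csv` and/or `census.csv` from `dir` and runs
#' the full validation on whichever are present.
#'
#' @param dir directory containing input CSVs.
#' @return invisibly, a named list of the validated tables.
#' @export
validate_dir <- function(dir) {
  out <- list()
  rp <- file.path(dir, "roster.csv")
  ip <- file.path(dir, "interactions.csv")
  cp <- file.path(dir, "census.csv")
  if (file.exists(rp)) out$roster <- read_roster(rp)
  if (file.exists(ip)) {
    if (is.null(out$roster)) stop("interactions.csv requires roster.csv")
    out$interactions <- read_interactions(ip, out$roster)
  }
  if (file.exists(cp)) out$census <- read_census(cp)
  if (!length(out)) stop("no recognised input files in ", dir)
  invisible(out)
}
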