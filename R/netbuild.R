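#' @title Daily network construction and sex-partitioned degree metrics
#' @name netbuild
NULL

#' Build per-community, per-day directed weighted networks
#'
#' One adjacency matrix per (community, day): `W[i, j]` is the number of
#' interactions individual `i` initiated toward individual `j` on that day.
#' The node order of a community is the same on every day (the full adult
#' roster of the community, sorted by id); individuals with no interactions on
#' a day contribute zero rows/columns, so matrices are conformable across days
#' as required by the temporal matrix correlations. Days with no records at
#' all still yield an (all-zero) network.
#'
#' @param records validated interactions table.
#' @param roster validated roster; juveniles are excluded from the node set.
#' @param days integer vector of days to emit; defaults to `1:max(day)` over
#'   the whole record table (or `1` if there are no records).
#' @param iclass `"all"` (default) sums affiliative and aggressive counts;
#'   `"affiliative"` or `"aggressive"` restricts to one class.
#' @return A list of `daily_network` objects, each a list with elements
#'   `community_id`, `day`, `node_order`, `W`.
#' @export
build_daily_networks <- function(records, roster, days = NULL,
                                 iclass = c("all", "affiliative", "aggressive")) {
  iclass <- match.arg(iclass)
  if (iclass != "all") records <- records[records$iclass == iclass, , drop = FALSE]
  if (is.null(days))
    days <- seq_len(max(c(1L, records$day)))
  adults <- roster[roster$sex != "juvenile", , drop = FALSE]
  comms <- sort(unique(adults$community_id))
  nets <- list()
  for (cm in comms) {
    ids <- sort(adults$id[adults$community_id == cm])
    n <- length(ids)
    rc <- records[records$community_id == cm, , drop = FALSE]
    for (d in days) {
      W <- matrix(0L, n, n, dimnames = list(ids, ids))
      rd <- rc[rc$day == d, , drop = FALSE]
      if (nrow(rd)) {
        i <- match(rd$initiator_id, ids)
        j <- match(rd$receiver_id, ids)
        for (k in seq_along(i)) W[i[k], j[k]] <- W[i[k], j[k]] + rd$count[k]
      }
      nets[[length(nets) + 1L]] <- structure(
        list(community_id = cm, day = d, node_order = ids, W = W),
        class = "daily_network")
    }
  }
  nets
}

#' @export
print.daily_network <- function(x, ...) {
  cat("daily_network: community", x$community_id, "day", x$day,
      "|", length(x$node_order), "nodes,", sum(x$W), "interactions\n")
  invisible(x)
}

#' Sex-partitioned degree metrics for focal individuals
#'
#' For each focal node of a daily network, four weighted degree counts broken
#' down by partner sex: in-degree from males, in-degree from females,
#' out-degree toward males and out-degree toward females. Together these
#' summarise aggression among males and affiliative behaviour between the
#' sexes. By default metrics are computed for male focals only, which is what
#' the downstream count models analyse.
#'
#' @param net a `daily_network`.
#' @param roster validated roster giving the sex of every node.
#' @param focal_sex sex of focal individuals (default `"male"`).
#' @return Data frame of class `degree_records` with columns `community_id`,
#'   `day`, `focal_id`, `metric`, `value`, `manipulated`.
#' @export
degree_metrics <- function(net, roster, focal_sex = "male") {
  ids <- net$node_order
  sex <- roster$sex[match(ids, roster$id)]
  if (any(is.na(sex))) stop("node(s) with unknown sex: ",
                            paste(ids[is.na(sex)], collapse = ", "))
  manip <- roster$manipulated[match(ids, roster$id)]
  W <- net$W
  males <- sex == "male"
  females <- sex == "female"
  focals <- which(sex == focal_sex)
  res <- lapply(focals, function(v) {
    data.frame(
      community_id = net$community_id, day = net$day, focal_id = ids[v],
      metric = c("in_from_males", "in_from_females",
                 "out_to_males", "out_to_females"),
      value = c(sum(W[males, v]) - if (males[v]) W[v, v] else 0L,
                sum(W[females, v]) - if (females[v]) W[v, v] else 0L,
                sum(W[v, males]) - if (males[v]) W[v, v] else 0L,
                sum(W[v, females]) - if (females[v]) W[v, v] else 0L),
      manipulated = manip[v], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(community_id = character(), day = integer(),
                      focal_id = character(), metric = character(),
                      value = integer(), manipulated = logical())
  rownames(out) <- NULL
  class(out) <- c("degree_records", "data.frame")
  out
}

#' @rdname degree_metrics
#' @param nets list of `daily_network` objects.
#' @return `degree_records_all()`: one stacked `degree_records` table.
#' @export
degree_records_all <- function(nets, roster, focal_sex = "male") {
  out <- do.call(rbind, lapply(nets, degree_metrics, roster = roster,
                               focal_sex = focal_sex))
  rownames(out) <- NULL
  class(out) <- c("degree_records", "data.frame")
  out
}
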