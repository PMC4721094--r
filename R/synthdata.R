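#' @title Seeded synthetic-data generator emulating the field study design
#' @description Generates Part I interaction records (modular communities of
#'   shell-dwelling groups with nearest-neighbour border conflicts, male-only
#'   long-range forays, a mid-study nest augmentation of one male per
#'   community and optional late heterospecific takeovers) and Part II census
#'   tables (nine-arm shell manipulation with five censuses at 3-day
#'   intervals, arm-dependent territory loss and membership turnover), so the
#'   whole analysis pipeline can be exercised and calibrated without the
#'   field data.
#' @name synthdata
NULL

#' Configuration for the Part I interaction generator
#'
#' Defaults emulate the observational design: five communities of eight
#' social groups laid out along a shell-bed transect (a 1-D lattice whose
#' adjacency defines nearest neighbours), each group holding one to three
#' adult males, one to five adult females and up to two juveniles; eight
#' daily observation sessions of equal effort; the shell nest of one male per
#' community augmented after the day-3 observation so the manipulation acts
#' from day 4.
#'
#' Interaction rates are per ordered adult dyad per day: `lambda_within`
#' inside a group, `lambda_neighbour` for border conflicts between adjacent
#' groups, and `lambda_male_longrange` for male-initiated forays to
#' non-adjacent groups (females do not leave their territories). From day
#' `manipulation_day + 1`, rates of dyads involving the manipulated male are
#' scaled by the matching effect multiplier (incoming from males/females,
#' outgoing to males/females). `takeover_hazard_postday5` is the daily
#' probability, from day 5 on, that a heterospecific usurps the augmented
#' territory and the community's records are truncated from that day.
#'
#' @param n_communities,groups_per_community,days design size.
#' @param males_per_group,females_per_group,juveniles_per_group integer sets
#'   sampled uniformly per group.
#' @param manipulation_day last pre-manipulation day.
#' @param lambda_within,lambda_neighbour,lambda_male_longrange Poisson means.
#' @param effect_multipliers named numeric vector `in_males`, `in_females`,
#'   `out_males`, `out_females` (all > 0); 1 = no manipulation effect.
#' @param dyad_sd standard deviation (log scale) of a persistent lognormal
#'   per-dyad rate multiplier, drawn once per ordered dyad and held fixed
#'   across days. This emulates stable dyadic preferences — the reason
#'   consecutive-day networks correlate even within sub-groups — and induces
#'   the overdispersion in daily counts that the Poisson-lognormal model
#'   absorbs. The multiplier has mean 1, so expected rates stay at the
#'   configured lambdas; 0 disables it.
#' @param takeover_hazard_postday5 daily takeover probability from day 5.
#' @param class_flip_prob probability that an interaction's behavioural class
#'   is flipped from the sex-composition default (male-male pairs aggressive,
#'   all other dyads affiliative).
#' @param seed integer seed.
#' @return validated list of class `part1_config`.
#' @export
part1_config <- function(n_communities = 5, groups_per_community = 8,
                         males_per_group = 1:3, females_per_group = 1:5,
                         juveniles_per_group = 0:2, days = 8,
                         manipulation_day = 3,
                         lambda_within = 1.5, lambda_neighbour = 0.1,
                         lambda_male_longrange = 0.02,
                         effect_multipliers = c(in_males = 3, in_females = 3,
                                                out_males = 3, out_females = 3),
                         dyad_sd = 0.8,
                         takeover_hazard_postday5 = 0.2,
                         class_flip_prob = 0, seed = 1L) {
  cfg <- list(n_communities = n_communities,
              groups_per_community = groups_per_community,
              males_per_group = males_per_group,
              females_per_group = females_per_group,
              juveniles_per_group = juveniles_per_group,
              days = days, manipulation_day = manipulation_day,
              lambda_within = lambda_within,
              lambda_neighbour = lambda_neighbour,
              lambda_male_longrange = lambda_male_longrange,
              effect_multipliers = effect_multipliers, dyad_sd = dyad_sd,
              takeover_hazard_postday5 = takeover_hazard_postday5,
              class_flip_prob = class_flip_prob, seed = as.integer(seed))
  rates <- c(lambda_within, lambda_neighbour, lambda_male_longrange)
  if (any(rates < 0)) stop("interaction rates must be >= 0")
  need <- c("in_males", "in_females", "out_males", "out_females")
  if (!all(need %in% names(effect_multipliers)) ||
      any(effect_multipliers <= 0))
    stop("effect_multipliers must be positive and named ",
         paste(need, collapse = ", "))
  if (takeover_hazard_postday5 < 0 || takeover_hazard_postday5 > 1)
    stop("takeover_hazard_postday5 must be a probability")
  if (dyad_sd < 0) stop("dyad_sd must be >= 0")
  if (manipulation_day < 1 || manipulation_day >= days)
    stop("manipulation_day must lie inside the study window")
  if (n_communities < 1 || groups_per_community < 1 || days < 2)
    stop("design sizes out of range")
  class(cfg) <- "part1_config"
  cfg
}

#' Generate Part I roster and interaction records
#'
#' @param cfg `part1_config`.
#' @return list with `roster` (validated roster, juveniles included),
#'   `interactions` (validated records), and `takeover_day` (named integer
#'   vector per community, `NA` when no takeover happened).
#' @export
generate_part1 <- function(cfg = part1_config()) {
  stopifnot(inherits(cfg, "part1_config"))
  set.seed(cfg$seed)
  rosters <- list(); dyads <- list()
  takeover <- stats::setNames(rep(NA_integer_, cfg$n_communities),
                              sprintf("c%02d", seq_len(cfg$n_communities)))
  for (ci in seq_len(cfg$n_communities)) {
    cm <- sprintf("c%02d", ci)
    rows <- list()
    for (gi in seq_len(cfg$groups_per_community)) {
      gid <- sprintf("%s_g%02d", cm, gi)
      nm <- sample_one(cfg$males_per_group)
      nf <- sample_one(cfg$females_per_group)
      nj <- sample_one(cfg$juveniles_per_group)
      mk <- function(sex, n, tag) if (n > 0)
        data.frame(id = sprintf("%s_%s%d", gid, tag, seq_len(n)), sex = sex,
                   group_id = gid, community_id = cm, pos = gi,
                   manipulated = FALSE, stringsAsFactors = FALSE)
      rows[[gi]] <- do.call(rbind, Filter(Negate(is.null), list(
        mk("male", nm, "m"), mk("female", nf, "f"), mk("juvenile", nj, "j"))))
    }
    ros <- do.call(rbind, rows)
    males <- which(ros$sex == "male")
    ros$manipulated[males[sample.int(length(males), 1)]] <- TRUE
    rosters[[ci]] <- ros
    ## per-dyad base rates over the ordered adult dyads of this community
    ad <- ros[ros$sex != "juvenile", , drop = FALSE]
    n <- nrow(ad)
    ii <- rep(seq_len(n), each = n); jj <- rep(seq_len(n), times = n)
    keep <- ii != jj
    ii <- ii[keep]; jj <- jj[keep]
    same <- ad$group_id[ii] == ad$group_id[jj]
    adj <- abs(ad$pos[ii] - ad$pos[jj]) == 1
    rate <- ifelse(same, cfg$lambda_within,
                   ifelse(adj, cfg$lambda_neighbour,
                          ifelse(ad$sex[ii] == "male",
                                 cfg$lambda_male_longrange, 0)))
    ## persistent dyadic preference: mean-1 lognormal frailty fixed across days
    if (cfg$dyad_sd > 0)
      rate <- rate * stats::rlnorm(length(rate), -cfg$dyad_sd^2 / 2,
                                   cfg$dyad_sd)
    manip_id <- ad$id[ad$manipulated]
    mult <- rep(1, length(ii))
    to_manip <- ad$id[jj] == manip_id
    from_manip <- ad$id[ii] == manip_id
    mult[to_manip & ad$sex[ii] == "male"] <- cfg$effect_multipliers["in_males"]
    mult[to_manip & ad$sex[ii] == "female"] <- cfg$effect_multipliers["in_females"]
    mult[from_manip & ad$sex[jj] == "male"] <- cfg$effect_multipliers["out_males"]
    mult[from_manip & ad$sex[jj] == "female"] <- cfg$effect_multipliers["out_females"]
    iclass <- ifelse(ad$sex[ii] == "male" & ad$sex[jj] == "male",
                     "aggressive", "affiliative")
    dyads[[ci]] <- list(cm = cm, init = ad$id[ii], recv = ad$id[jj],
                        rate = rate, mult = mult, iclass = iclass)
  }
  ## daily Poisson draws, manipulation effect from manipulation_day + 1,
  ## optional takeover truncation from day 5 on
  recs <- list()
  for (ci in seq_len(cfg$n_communities)) {
    d <- dyads[[ci]]
    for (day in seq_len(cfg$days)) {
      if (day >= 5 && is.na(takeover[ci]) &&
          stats::runif(1) < cfg$takeover_hazard_postday5)
        takeover[ci] <- day
      if (!is.na(takeover[ci]) && day >= takeover[ci]) next
      rate <- d$rate * (if (day > cfg$manipulation_day) d$mult else 1)
      cnt <- stats::rpois(length(rate), rate)
      hit <- cnt > 0
      if (!any(hit)) next
      cl <- d$iclass[hit]
      if (cfg$class_flip_prob > 0) {
        flip <- stats::runif(sum(hit)) < cfg$class_flip_prob
        cl[flip] <- ifelse(cl[flip] == "aggressive", "affiliative", "aggressive")
      }
      recs[[length(recs) + 1L]] <- data.frame(
        community_id = d$cm, day = day, initiator_id = d$init[hit],
        receiver_id = d$recv[hit], iclass = cl, count = cnt[hit],
        stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, rosters)
  roster$pos <- NULL
  rownames(roster) <- NULL
  roster <- validate_roster(roster)
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(community_id = character(), day = integer(),
                          initiator_id = character(), receiver_id = character(),
                          iclass = character(), count = integer())
  records <- validate_interactions(records, roster)
  list(roster = roster, interactions = records, takeover_day = takeover)
}

## sample uniformly from a set given as an integer vector (handles length 1)
sample_one <- function(set) if (length(set) == 1L) set else
  set[sample.int(length(set), 1)]

#' Configuration for the Part II census generator
#'
#' Defaults emulate the manipulation experiment: 173 experimental groups
#' spread as evenly as possible over the nine arms; a single resident male
#' per group with one or two females (probabilities 78/173 and 95/173) and
#' zero, one or two juveniles (51/173, 85/173, 37/173); five censuses, the
#' first before manipulation and the rest at 3-day intervals. Territory loss
#' is an absorbing state whose overall per-arm probability is set by
#' `loss_prob` (converted internally to a constant per-census hazard over
#' observations 2-5); default probabilities follow the experiment's observed
#' pattern, with elevated loss only in the strong adding/combination arms.
#' Between consecutive censuses surviving groups gain a female with the
#' arm-specific `female_join` probability (elevated where nests were made
#' more attractive), gain a male with `male_join`, and lose members with the
#' `*_leave` probabilities; juveniles turn over at a common background rate.
#'
#' @param n_groups number of experimental groups (default 173).
#' @param arm_props allocation proportions over the nine arms (default equal).
#' @param female_probs probabilities of 1 or 2 initial females.
#' @param juvenile_probs probabilities of 0, 1 or 2 initial juveniles.
#' @param loss_prob named per-arm overall territory-loss probability.
#' @param female_join,male_join named per-arm per-interval join probabilities.
#' @param female_leave,male_leave,juvenile_join,juvenile_leave scalar
#'   background per-interval probabilities.
#' @param n_obs censuses per group (default 5).
#' @param obs_spacing_days days between post-manipulation censuses (default 3).
#' @param heterospecific_background probability a heterospecific is seen
#'   inside a territory that has not been taken over.
#' @param seed integer seed.
#' @return validated list of class `part2_config`.
#' @export
part2_config <- function(n_groups = 173,
                         arm_props = stats::setNames(rep(1 / 9, 9), TREATMENTS),
                         female_probs = c(`1` = 78 / 173, `2` = 95 / 173),
                         juvenile_probs = c(`0` = 51 / 173, `1` = 85 / 173,
                                            `2` = 37 / 173),
                         loss_prob = c(C1 = 0.05, C2 = 0.05, C3 = 0.05,
                                       R2 = 0.05, R4 = 0.05, A2 = 0.05,
                                       A4 = 0.45, AR2 = 0.25, AR4 = 0.4),
                         female_join = c(C1 = 0.05, C2 = 0.05, C3 = 0.05,
                                         R2 = 0.05, R4 = 0.05, A2 = 0.05,
                                         A4 = 0.3, AR2 = 0.3, AR4 = 0.3),
                         male_join = c(C1 = 0.01, C2 = 0.01, C3 = 0.01,
                                       R2 = 0.01, R4 = 0.01, A2 = 0.01,
                                       A4 = 0.05, AR2 = 0.05, AR4 = 0.05),
                         female_leave = 0.02, male_leave = 0.01,
                         juvenile_join = 0.05, juvenile_leave = 0.05,
                         n_obs = 5, obs_spacing_days = 3,
                         heterospecific_background = 0.02, seed = 1L) {
  female_probs <- female_probs / sum(female_probs)
  juvenile_probs <- juvenile_probs / sum(juvenile_probs)
  arm_props <- arm_props / sum(arm_props)
  cfg <- list(n_groups = n_groups, arm_props = arm_props,
              female_probs = female_probs, juvenile_probs = juvenile_probs,
              loss_prob = loss_prob, female_join = female_join,
              male_join = male_join, female_leave = female_leave,
              male_leave = male_leave, juvenile_join = juvenile_join,
              juvenile_leave = juvenile_leave, n_obs = n_obs,
              obs_spacing_days = obs_spacing_days,
              heterospecific_background = heterospecific_background,
              seed = as.integer(seed))
  probs <- c(loss_prob, female_join, male_join, female_leave, male_leave,
             juvenile_join, juvenile_leave, heterospecific_background)
  if (any(probs < 0 | probs > 1)) stop("all rates must be probabilities in [0, 1]")
  if (!all(TREATMENTS %in% names(loss_prob)) ||
      !all(TREATMENTS %in% names(female_join)) ||
      !all(TREATMENTS %in% names(male_join)) ||
      !all(TREATMENTS %in% names(arm_props)))
    stop("per-arm parameters must be named with all nine treatment codes")
  if (n_groups < 9) stop("need at least one group per arm")
  if (n_obs < 2) stop("need at least two observations")
  class(cfg) <- "part2_config"
  cfg
}

#' Generate a Part II census table
#'
#' @param cfg `part2_config`.
#' @return validated `census` table (5 rows per group, monotone
#'   `territory_lost`). Arm allocation is deterministic in size (largest
#'   remainder over `arm_props`) with a random shuffle of which group gets
#'   which arm.
#' @export
generate_part2 <- function(cfg = part2_config()) {
  stopifnot(inherits(cfg, "part2_config"))
  set.seed(cfg$seed)
  ## largest-remainder allocation of n_groups over the arms
  quota <- cfg$n_groups * cfg$arm_props
  sizes <- floor(quota)
  rem <- cfg$n_groups - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  arms <- sample(rep(names(sizes), times = sizes))
  rows <- list()
  for (g in seq_len(cfg$n_groups)) {
    arm <- arms[g]
    gid <- sprintf("g%03d", g)
    nf <- as.integer(sample(names(cfg$female_probs), 1,
                            prob = cfg$female_probs))
    nj <- as.integer(sample(names(cfg$juvenile_probs), 1,
                            prob = cfg$juvenile_probs))
    nm <- 1L
    ## constant per-census hazard reproducing the overall loss probability
    hazard <- 1 - (1 - cfg$loss_prob[arm])^(1 / (cfg$n_obs - 1))
    lost <- FALSE
    for (ob in seq_len(cfg$n_obs)) {
      if (ob > 1 && !lost) {
        if (stats::runif(1) < hazard) {
          lost <- TRUE
        } else {
          nf <- nf + stats::rbinom(1, 1, cfg$female_join[arm]) -
            (if (nf > 0) stats::rbinom(1, 1, cfg$female_leave) else 0L)
          nm <- nm + stats::rbinom(1, 1, cfg$male_join[arm]) -
            (if (nm > 1) stats::rbinom(1, 1, cfg$male_leave) else 0L)
          nj <- nj + stats::rbinom(1, 1, cfg$juvenile_join) -
            (if (nj > 0) stats::rbinom(1, 1, cfg$juvenile_leave) else 0L)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = gid, treatment = arm, obs_index = ob,
        n_males = if (lost) 0L else nm, n_females = if (lost) 0L else nf,
        n_juveniles = if (lost) 0L else nj, territory_lost = lost,
        heterospecific_present = lost ||
          stats::runif(1) < cfg$heterospecific_background,
        stringsAsFactors = FALSE)
    }
  }
  census <- do.call(rbind, rows)
  rownames(census) <- NULL
  validate_census(census)
}
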