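test_that("identical seeds give byte-identical synthetic datasets", {
  a <- generate_part1(part1_config(seed = 13))
  b <- generate_part1(part1_config(seed = 13))
  expect_identical(a, b)
  c1 <- generate_part2(part2_config(seed = 13))
  c2 <- generate_part2(part2_config(seed = 13))
  expect_identical(c1, c2)
  ## and different seeds differ
  expect_false(identical(a$interactions,
                         generate_part1(part1_config(seed = 14))$interactions))
})

test_that("communities are modular: most interactions stay within groups", {
  cfg <- function(s) part1_config(n_communities = 2, groups_per_community = 6,
                                  lambda_within = 5, lambda_neighbour = 0.5,
                                  lambda_male_longrange = 0.05,
                                  takeover_hazard_postday5 = 0, seed = s)
  frac <- vapply(1:40, function(s) {
    p1 <- generate_part1(cfg(s))
    ros <- p1$roster
    gi <- ros$group_id[match(p1$interactions$initiator_id, ros$id)]
    gr <- ros$group_id[match(p1$interactions$receiver_id, ros$id)]
    sum(p1$interactions$count[gi == gr]) / sum(p1$interactions$count)
  }, 0)
  expect_gt(mean(frac), 0.8)
})

test_that("null manipulation leaves day 3 and day 4 exchangeable", {
  cfg <- function(s) part1_config(
    n_communities = 2, days = 4, takeover_hazard_postday5 = 0,
    effect_multipliers = c(in_males = 1, in_females = 1,
                           out_males = 1, out_females = 1), seed = s)
  d3 <- d4 <- numeric(60)
  for (s in 1:60) {
    p1 <- generate_part1(cfg(s))
    d3[s] <- sum(p1$interactions$count[p1$interactions$day == 3])
    d4[s] <- sum(p1$interactions$count[p1$interactions$day == 4])
  }
  dd <- d4 - d3
  expect_lt(abs(mean(dd)), 3 * stats::sd(dd) / sqrt(length(dd)))
})

test_that("manipulation multiplies the focal male's rates from day 4", {
  cfg <- part1_config(n_communities = 3, dyad_sd = 0,
                      takeover_hazard_postday5 = 0, seed = 19)
  p1 <- generate_part1(cfg)
  ros <- p1$roster
  man <- ros$id[ros$manipulated]
  rec <- p1$interactions
  inv <- rec$initiator_id %in% man | rec$receiver_id %in% man
  pre <- sum(rec$count[inv & rec$day %in% 1:3]) / 3
  post <- sum(rec$count[inv & rec$day %in% 4:6]) / 3
  ## multiplier 3 on every dyad involving the manipulated male
  expect_gt(post / pre, 2)
})

test_that("takeovers truncate records and only occur after day 4", {
  cfg <- part1_config(n_communities = 4, takeover_hazard_postday5 = 1,
                      seed = 2)
  p1 <- generate_part1(cfg)
  expect_true(all(p1$takeover_day == 5))
  expect_true(all(p1$interactions$day <= 4))
  none <- generate_part1(part1_config(n_communities = 2,
                                      takeover_hazard_postday5 = 0, seed = 2))
  expect_true(all(is.na(none$takeover_day)))
})

test_that("juveniles are rostered but never interact; one focal male per community", {
  p1 <- generate_part1(part1_config(seed = 4))
  juv <- p1$roster$id[p1$roster$sex == "juvenile"]
  expect_gt(length(juv), 0)
  expect_false(any(p1$interactions$initiator_id %in% juv |
                     p1$interactions$receiver_id %in% juv))
  man <- p1$roster[p1$roster$manipulated, ]
  expect_equal(nrow(man), 5L)
  expect_equal(sort(unique(man$community_id)), sort(unique(p1$roster$community_id)))
  expect_true(all(man$sex == "male"))
})

test_that("initial composition matches the stated female/juvenile distribution", {
  cen <- generate_part2(part2_config(seed = 27))
  first <- cen[cen$obs_index == 1, ]
  n1f <- sum(first$n_females == 1)
  ## exact binomial 99% CI around the configured 78/173 probability
  ci <- stats::qbinom(c(0.005, 0.995), 173, 78 / 173)
  expect_gte(n1f, ci[1]); expect_lte(n1f, ci[2])
  n0j <- sum(first$n_juveniles == 0)
  cij <- stats::qbinom(c(0.005, 0.995), 173, 51 / 173)
  expect_gte(n0j, cij[1]); expect_lte(n0j, cij[2])
  expect_true(all(first$n_males == 1))
})

test_that("per-arm loss frequencies match the configured probabilities", {
  target <- c(C1 = 0.05, C2 = 0.05, C3 = 0.05, R2 = 0.05, R4 = 0.05,
              A2 = 0.05, A4 = 0.45, AR2 = 0.25, AR4 = 0.4)
  lost <- stats::setNames(rep(0, 9), TREATMENTS)
  n <- stats::setNames(rep(0, 9), TREATMENTS)
  for (s in 1:100) {
    out <- to_outcomes(generate_part2(part2_config(seed = 700 + s)))
    tab <- tapply(out$lost, out$treatment, sum)
    cnt <- table(out$treatment)
    lost[names(tab)] <- lost[names(tab)] + tab
    n[names(cnt)] <- n[names(cnt)] + cnt
  }
  phat <- lost / n
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(phat - target[names(phat)]) < 3 * se[names(phat)]))
})
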