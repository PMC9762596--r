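# Hand-built fixtures: clade-level count matrices with known structure,
# wrapped via toy_clade_matrix()/toy_metadata() from the helpers.

make_hosts <- function(n_per_cell, study = "ZAM2", trt = "ZD") {
  cells <- expand.grid(age = c("young", "old"), arm = c("ZA", trt),
                       stringsAsFactors = FALSE)
  hosts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(age = cells$age[i], diet = cells$arm[i], study = study,
               rep = seq_len(n_per_cell))))
  hosts$host_id <- sprintf("M%02d", seq_len(nrow(hosts)))
  hosts$il6 <- pmax(0, 60 + 40 * (hosts$age == "old") +
                      30 * (hosts$diet == "ZD") + rnorm(nrow(hosts), 0, 20))
  hosts
}

test_that("age battery detects a planted age effect and nothing else systematic", {
  set.seed(30)
  hosts <- make_hosts(10)
  md <- toy_metadata(hosts)
  old <- md$age == "old"
  n_clades <- 20
  hit_planted <- 0; other_hits <- 0
  for (rep in 1:100) {
    mu <- matrix(exp(3), nrow(md), n_clades)
    mu[old, 1] <- exp(3 + 1.5)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow(md),
                     dimnames = list(md$sample_id, paste0("c", 1:n_clades)))
    res <- run_age_battery(toy_clade_matrix(counts), md)
    sig <- significant_clades(res)
    if ("c1" %in% sig) hit_planted <- hit_planted + 1
    other_hits <- other_hits + length(setdiff(sig, "c1"))
  }
  expect_gte(hit_planted, 95)
  # per-replicate false positives stay near the BH budget
  expect_lt(other_hits / 100, 1)
})

test_that("identical age groups yield zero significant clades", {
  set.seed(31)
  hosts <- make_hosts(5)
  md <- toy_metadata(hosts)
  counts <- matrix(rnbinom(nrow(md) * 10, mu = 30, size = 2), nrow(md),
                   dimnames = list(md$sample_id, paste0("c", 1:10)))
  counts[md$age == "old", ] <- counts[md$age == "young", ]  # exact copies
  res <- run_age_battery(toy_clade_matrix(counts), md)
  expect_identical(significant_clades(res), character(0))
  expect_true(all(res$p[res$excluded_reason == "none"] > 0.99))
})

test_that("degenerate clades are excluded with a reason, not fitted", {
  set.seed(32)
  hosts <- make_hosts(3)
  md <- toy_metadata(hosts)
  counts <- matrix(rnbinom(nrow(md) * 3, mu = 30, size = 2), nrow(md),
                   dimnames = list(md$sample_id, c("ok", "zero", "sparse")))
  counts[, "zero"] <- 0
  counts[, "sparse"] <- 0; counts[1:2, "sparse"] <- 5
  res <- run_age_battery(toy_clade_matrix(counts), md)
  expect_identical(res$excluded_reason[match(c("zero", "sparse"), res$clade_id)],
                   c("degenerate", "degenerate"))
  expect_true(is.na(res$q[res$clade_id == "zero"]))
  expect_false(any(res$clade_id[res$significant] %in% c("zero", "sparse")))
})

test_that("diet battery finds a planted effect in its own family only", {
  set.seed(33)
  hosts <- make_hosts(10)           # one study (ZAM2); ZAM1 families skipped
  md <- toy_metadata(hosts)
  target <- md$age == "old" & md$diet == "ZD"
  n_clades <- 8
  own <- 0; other <- 0
  for (rep in 1:40) {
    b <- rnorm(nrow(hosts), 0, 0.3)
    names(b) <- hosts$host_id
    mu <- matrix(exp(3 + b[md$host_id]), nrow(md), n_clades)
    mu[target, 1] <- mu[target, 1] * exp(1.5)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow(md),
                     dimnames = list(md$sample_id, paste0("c", 1:n_clades)))
    res <- suppressMessages(run_diet_battery(toy_clade_matrix(counts), md))
    sig <- res[res$significant, ]
    if (any(sig$clade_id == "c1" & sig$family == "old.ZAM2")) own <- own + 1
    if (any(sig$family != "old.ZAM2")) other <- other + 1
  }
  expect_gte(own, 36)               # >= 90% detection in the planted family
  expect_lte(other, 8)              # rarely anywhere else
})

test_that("host-only structure is absorbed by the random intercept", {
  set.seed(34)
  hosts <- make_hosts(6)
  md <- toy_metadata(hosts)
  # identical counts at wk0 and wk6 per host, arms exchangeable: never significant
  base <- rnbinom(nrow(hosts) * 5, mu = 40, size = 2)
  counts <- matrix(base[rep(seq_len(nrow(hosts) * 5), times = 1)],
                   nrow(hosts), 5)
  counts <- counts[rep(seq_len(nrow(hosts)), 2), ]  # wk0 == wk6
  dimnames(counts) <- list(toy_metadata(hosts)$sample_id, paste0("c", 1:5))
  md2 <- toy_metadata(hosts)
  counts <- counts[md2$sample_id, , drop = FALSE]
  # make treated arm an exact copy of the control arm, host by host
  for (age in c("young", "old")) {
    ctrl <- hosts$host_id[hosts$age == age & hosts$diet == "ZA"]
    trt <- hosts$host_id[hosts$age == age & hosts$diet == "ZD"]
    for (k in seq_along(trt)) for (tp in c("wk0", "wk6"))
      counts[paste(trt[k], tp, sep = "_"), ] <-
        counts[paste(ctrl[k], tp, sep = "_"), ]
  }
  res <- suppressMessages(run_diet_battery(toy_clade_matrix(counts), md2))
  expect_identical(significant_clades(res), character(0))

  # host baseline offsets alone (no diet effect) are rarely called
  det <- 0
  for (rep in 1:30) {
    b <- rnorm(nrow(hosts), 0, 1)
    names(b) <- hosts$host_id
    mu <- exp(3 + b[md2$host_id])
    cnt <- matrix(rnbinom(nrow(md2) * 2, mu = mu, size = 3), nrow(md2),
                  dimnames = list(md2$sample_id, c("c1", "c2")))
    r <- suppressMessages(run_diet_battery(toy_clade_matrix(cnt), md2))
    if (length(significant_clades(r)) > 0) det <- det + 1
  }
  expect_lt(det / 30, 0.25)
})

test_that("diet battery skips families without enough hosts per arm", {
  set.seed(35)
  hosts <- make_hosts(3)            # ZAM2 only
  md <- toy_metadata(hosts)
  counts <- matrix(rnbinom(nrow(md) * 2, mu = 30, size = 2), nrow(md),
                   dimnames = list(md$sample_id, c("c1", "c2")))
  expect_message(res <- run_diet_battery(toy_clade_matrix(counts), md),
                 "skipping family young.ZAM1")
  expect_setequal(attr(res, "skipped"), c("young.ZAM1", "old.ZAM1"))
  expect_setequal(unique(res$family), c("young.ZAM2", "old.ZAM2"))
})

test_that("IL-6 battery uses week 6 only and detects a planted slope", {
  set.seed(36)
  hosts <- make_hosts(10)
  md <- toy_metadata(hosts)
  wk6 <- md$timepoint == "wk6"

  # wk0 rows are ignored: garbage there must not change the result
  mu <- matrix(exp(3), nrow(md), 4)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow(md),
                   dimnames = list(md$sample_id, paste0("c", 1:4)))
  counts2 <- counts; counts2[!wk6, ] <- counts2[!wk6, ] * 50
  r1 <- run_il6_battery(toy_clade_matrix(counts), md)
  r2 <- run_il6_battery(toy_clade_matrix(counts2), md)
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$p, r2$p)

  # planted positive slope 0.02 / (pg/ml) over an IL-6 range of ~100 pg/ml
  md$il6[wk6] <- runif(sum(wk6), 10, 110)
  hit <- 0
  for (rep in 1:30) {
    mu <- matrix(exp(3), nrow(md), 8)
    mu[wk6, 1] <- exp(3 + 0.02 * (md$il6[wk6] - mean(md$il6[wk6])))
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow(md),
                  dimnames = list(md$sample_id, paste0("c", 1:8)))
    r <- run_il6_battery(toy_clade_matrix(cnt), md)
    sig <- r[r$significant & r$clade_id == "c1", ]
    if (nrow(sig) > 0 && all(sig$slope > 0)) hit <- hit + 1
  }
  expect_gte(hit / 30, 0.9)

  # constant IL-6 in a group: battery skipped for that group
  md3 <- md; md3$il6[wk6 & md3$age == "old"] <- 50
  expect_message(r3 <- run_il6_battery(toy_clade_matrix(counts), md3),
                 "skipping old")
  expect_setequal(unique(r3$family), "young")
})
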