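# Survey-weighted CSMFs, CHERG-style mapping, top-k ranking.

# small fully-assigned allocation built directly
toy_allocation <- function(causes, weights,
                           stratum = rep("child", length(causes)),
                           des_stratum = rep("S1", length(causes)),
                           des_psu = rep("P1", length(causes))) {
  n <- length(causes)
  ids <- sprintf("r%02d", seq_len(n))
  rec <- va_records(data.frame(
    record_id = ids, live_birth = "yes",
    age_at_death_days = ifelse(stratum == "neonate", 5L, 100L),
    questionnaire_type = ifelse(stratum == "neonate", "neonatal", "child"),
    survey_weight = weights, stratum_id = des_stratum, psu_id = des_psu,
    stringsAsFactors = FALSE), tiny_codebook())
  alloc <- structure(list(
    assignments = NULL,
    allocations = data.frame(record_id = ids, stratum = stratum,
                             cause = causes, fraction = 1,
                             weight = weights, stringsAsFactors = FALSE),
    mode = "fractional"), class = "va_allocation")
  list(alloc = alloc, rec = rec)
}

test_that("equal weights give simple proportions", {
  x <- toy_allocation(c("A", "A", "B", "unspecified"), rep(1, 4))
  tab <- compute_csmf(x$alloc, x$rec, "all")
  f <- setNames(tab$fraction, tab$cause)
  expect_equal(unname(f[c("A", "B", "unspecified")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
  expect_equal(attr(tab, "n"), 4L)
})

test_that("weighted CSMF is the hand-computed ratio", {
  x <- toy_allocation(c("A", "A", "B", "unspecified"), c(3, 1, 1, 1))
  tab <- compute_csmf(x$alloc, x$rec, "all")
  f <- setNames(tab$fraction, tab$cause)
  expect_equal(unname(f[c("A", "B", "unspecified")]), c(4, 1, 1) / 6)
})

test_that("degenerate table: one cause only", {
  x <- toy_allocation(rep("A", 5), runif(5) + 0.5)
  tab <- compute_csmf(x$alloc, x$rec, "all")
  expect_equal(tab$fraction, 1)
  expect_error(compute_csmf(x$alloc, x$rec, "neonate"), "no records")
})

test_that("CSMFs are invariant to rescaling all weights", {
  set.seed(5)
  causes <- sample(c("A", "B", "C"), 30, replace = TRUE)
  w <- rlnorm(30)
  t1 <- compute_csmf(toy_allocation(causes, w)$alloc,
                     toy_allocation(causes, w)$rec, "all")
  t2 <- compute_csmf(toy_allocation(causes, w * 17)$alloc,
                     toy_allocation(causes, w * 17)$rec, "all")
  expect_equal(t1$fraction, t2$fraction, tolerance = 1e-12)
})

test_that("linearized SE matches binomial SE for iid single-stage design", {
  # uniform weights, each record its own PSU in one stratum: the Taylor
  # variance reduces to n/(n-1) * sum((y_i - p)^2)/n^2 = p(1-p)/(n-1)
  set.seed(6)
  n <- 400
  causes <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.3, 0.7))
  x <- toy_allocation(causes, rep(1, n),
                      des_psu = sprintf("P%03d", seq_len(n)))
  tab <- compute_csmf(x$alloc, x$rec, "all", se = TRUE)
  p <- tab$fraction[tab$cause == "A"]
  expect_equal(tab$se[tab$cause == "A"], sqrt(p * (1 - p) / (n - 1)),
               tolerance = 1e-10)
})

test_that("clustered design inflates the SE of a clustered cause", {
  # cause A concentrated in whole PSUs -> between-PSU variance dominates
  set.seed(7)
  n <- 200
  psu <- rep(sprintf("P%02d", 1:20), each = 10)
  causes <- ifelse(psu %in% sprintf("P%02d", 1:6), "A", "B")
  x <- toy_allocation(causes, rep(1, n), des_psu = psu)
  clustered <- compute_csmf(x$alloc, x$rec, "all", se = TRUE)
  y <- toy_allocation(sample(causes), rep(1, n),
                      des_psu = sprintf("P%03d", 1:n))
  iid <- compute_csmf(y$alloc, y$rec, "all", se = TRUE)
  expect_gt(clustered$se[clustered$cause == "A"],
            2 * iid$se[iid$cause == "A"])
})

test_that("cause mapping collapses categories and preserves the total", {
  x <- toy_allocation(c("birth_asphyxia", "birth_injury", "tetanus"),
                      c(5, 2, 3), stratum = rep("neonate", 3))
  tab <- compute_csmf(x$alloc, x$rec, "neonate")
  mapped <- map_causes(tab)
  f <- setNames(mapped$fraction, mapped$cause)
  expect_equal(unname(f["intrapartum-related complications"]), 0.7)
  expect_equal(sum(mapped$fraction), sum(tab$fraction), tolerance = 1e-12)
  # identity map leaves the table unchanged
  idmap <- setNames(tab$cause, tab$cause)
  expect_equal(map_causes(tab, idmap)$fraction, tab$fraction)
  # totality enforced
  expect_error(map_causes(tab, c(tetanus = "tetanus")), "birth_asphyxia")
})

test_that("ranking sorts, breaks ties by hierarchy order, truncates", {
  tab <- structure(data.frame(
    cause = c("malaria", "pneumonia", "diarrhea", "aids", "unspecified",
              "other_infections"),
    fraction = c(0.25, 0.18, 0.18, 0.1, 0.2, 0.09),
    stringsAsFactors = FALSE),
    age_group = "child", n = 100L, class = c("csmf_table", "data.frame"))
  ord <- default_hierarchies()$child$ordered_causes
  top2 <- rank_top(tab, 2, ord)
  expect_equal(top2$cause, c("malaria", "pneumonia"))  # tie: pneumonia first
  expect_equal(rank_top(tab, 10, ord)$cause,
               c("malaria", "pneumonia", "diarrhea", "aids"))
  # residual groups never ranked
  expect_false(any(grepl("unspecified|other", rank_top(tab, 10)$cause)))
})
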