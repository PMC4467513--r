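# Assignment walk, multi-cause group, redistribution.

make_records <- function(rows) {
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA
    r[all_cols]
  })
  va_records(do.call(rbind, rows), builtin_codebook())
}

test_that("first true non-group cause wins and stops evaluation", {
  rec <- make_records(list(base_record(
    "n1", age = 5,
    suckled_normally_first_2d = "yes", stopped_suckling = "yes",
    spasms = "yes",                           # tetanus
    cough = "yes", fast_breathing = "yes"     # also pneumonia
  )))
  asg <- va_assign(rec, trace = TRUE)
  expect_equal(asg$final_cause, "tetanus")
  tr <- asg$rule_trace[[1]]
  expect_equal(names(tr), "tetanus")  # nothing after tetanus was evaluated
})

test_that("group members accumulate; later non-group causes are masked", {
  rec <- make_records(list(base_record(
    "c1", age = 200,
    loose_stools = "yes", stools_per_day = 7,        # diarrhea (group)
    cough = "yes", fast_breathing = "yes",           # pneumonia (group)
    fever = "yes", stiff_neck = "yes"                # meningitis (later)
  )))
  asg <- va_assign(rec, trace = TRUE)
  expect_true(asg$pending)
  expect_setequal(asg$provisional[[1]], c("pneumonia", "diarrhea"))
  expect_true(is.na(asg$final_cause))
  expect_false("meningitis" %in% names(asg$rule_trace[[1]]))
})

test_that("no firing definition falls back to unspecified", {
  rec <- make_records(list(base_record("c2", age = 200, fever = "no")))
  asg <- va_assign(rec)
  expect_equal(asg$final_cause, "unspecified")
})

test_that("assign matches the evaluate-all-then-resolve oracle", {
  set.seed(99)
  cb <- builtin_codebook()
  defs <- builtin_definitions()
  hier <- default_hierarchies()
  kinds <- vapply(cb, `[[`, "", "kind")
  bins <- names(kinds)[kinds == "binary"]
  nums <- names(kinds)[kinds != "binary"]
  n <- 400
  rows <- lapply(seq_len(n), function(i) {
    r <- base_record(sprintf("r%04d", i), age = sample(0:1826, 1))
    for (b in sample(bins, sample(3:10, 1))) r[[b]] <- "yes"
    for (m in sample(nums, sample(0:3, 1))) r[[m]] <- sample(0:45, 1)
    r
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA
    r[all_cols]
  })
  rec <- va_records(do.call(rbind, rows), cb)
  asg <- va_assign(rec, hier, defs)
  item_cols <- intersect(codebook_ids(cb), names(rec))
  cols <- as.list(as.data.frame(rec)[item_cols])
  strata <- stratify(rec$age_at_death_days)
  for (i in seq_len(n)) {
    resp <- lapply(cols, `[[`, i)
    expected <- naive_assign(resp, hier[[strata[i]]], defs)
    expect_setequal(asg$provisional[[i]], expected)
  }
})

test_that("fractional redistribution splits 2:1 by pre-CSMF", {
  # three single-cause records set diarrhea:pneumonia weights 2:1, then a
  # pending {diarrhea, pneumonia} record must split 2/3 : 1/3
  rec <- make_records(list(
    base_record("a", age = 100, weight = 2, loose_stools = "yes",
                stools_per_day = 8),
    base_record("b", age = 100, weight = 1, cough = "yes",
                fast_breathing = "yes"),
    base_record("c", age = 100, weight = 3, loose_stools = "yes",
                stools_per_day = 8, cough = "yes", fast_breathing = "yes")
  ))
  asg <- va_assign(rec)
  expect_equal(sum(asg$pending), 1L)
  al <- va_redistribute(asg, rec, mode = "fractional")
  pc <- al$allocations[al$allocations$record_id == "c", ]
  expect_equal(pc$fraction[pc$cause == "diarrhea"], 2 / 3)
  expect_equal(pc$fraction[pc$cause == "pneumonia"], 1 / 3)
  expect_false(any(al$assignments$pending))
  # conservation: record weight fractions sum to one, total weight kept
  expect_equal(sum(pc$fraction), 1)
  expect_equal(sum(al$allocations$weight * al$allocations$fraction),
               sum(rec$survey_weight))
})

test_that("sampling mode is seed-reproducible and singleton sets resolve", {
  rec <- make_records(list(
    base_record("a", age = 100, weight = 2, loose_stools = "yes",
                stools_per_day = 8),
    base_record("b", age = 100, weight = 1, cough = "yes",
                fast_breathing = "yes"),
    base_record("c", age = 100, weight = 3, loose_stools = "yes",
                stools_per_day = 8, cough = "yes", fast_breathing = "yes"),
    base_record("m", age = 100, rash = "yes", fever = "yes",
                rash_on_face = "yes")        # singleton group set {measles}
  ))
  asg <- va_assign(rec)
  a1 <- va_redistribute(asg, rec, mode = "sample", seed = 11)
  a2 <- va_redistribute(asg, rec, mode = "sample", seed = 11)
  expect_identical(a1$assignments$final_cause, a2$assignments$final_cause)
  expect_equal(
    a1$assignments$final_cause[a1$assignments$record_id == "m"], "measles")
  expect_true(a1$assignments$final_cause[
    a1$assignments$record_id == "c"] %in% c("diarrhea", "pneumonia"))
  # no pending records: redistribution is the identity
  single <- va_assign(rec[rec$record_id != "c", ])
  al <- va_redistribute(single, rec)
  expect_equal(al$assignments$final_cause, single$final_cause)
})

test_that("all-zero pre-CSMFs split equally, with a message", {
  rec <- make_records(list(
    base_record("c", age = 100, weight = 4, loose_stools = "yes",
                stools_per_day = 8, cough = "yes", fast_breathing = "yes")
  ))
  asg <- va_assign(rec)
  expect_message(al <- va_redistribute(asg, rec), "splitting equally")
  expect_equal(sort(al$allocations$fraction), c(0.5, 0.5))
})

test_that("default hierarchies obey the published placement constraints", {
  h <- default_hierarchies()
  idx <- function(s, cz) match(cz, h[[s]]$ordered_causes)
  expect_true(idx("child", "pneumonia") < idx("child", "meningitis"))
  expect_true(idx("child", "meningitis") < idx("child", "malaria"))
  expect_true(idx("child", "malaria") < idx("child", "aids"))
  expect_false("malaria" %in% h$neonate$ordered_causes)
  expect_false("aids" %in% h$neonate$ordered_causes)
  expect_true(idx("neonate", "pneumonia") < idx("neonate", "sepsis"))
  expect_true(idx("neonate", "diarrhea") < idx("neonate", "sepsis"))
  defs <- builtin_definitions()
  for (x in h) expect_true(validate_hierarchy(x, defs))
})

test_that("validator rejects constraint-violating orders unless overridden", {
  defs <- builtin_definitions()
  bad <- va_hierarchy("child",
                      c("measles", "injury", "aids", "pneumonia",
                        "meningitis", "malaria", "diarrhea",
                        "other_infections"))
  expect_error(validate_hierarchy(bad, defs), "placement")
  expect_true(validate_hierarchy(bad, defs, allow_order_override = TRUE))
  noneo <- va_hierarchy("neonate", c("tetanus", "malaria"))
  expect_error(validate_hierarchy(noneo, defs), "must not assign")
  undef <- va_hierarchy("child", c("measles", "dragonpox"))
  expect_error(validate_hierarchy(undef, defs), "without a")
})

test_that("hierarchy config round-trips and enforces constraints on load", {
  h <- default_hierarchies()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hierarchies(h, path)
  h2 <- load_hierarchies(path)
  expect_equal(h2, h)
  cfg <- yaml::read_yaml(path)
  cfg$child$ordered_causes <-
    rev(cfg$child$ordered_causes)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(load_hierarchies(bad), "placement")
  cfg$allow_order_override <- TRUE
  ok <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, ok)
  expect_silent(load_hierarchies(ok))
})
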