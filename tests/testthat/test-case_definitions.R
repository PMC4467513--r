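# Predicate engine and the shipped case definitions.

test_that("evaluation matches a brute-force interpreter on random trees", {
  set.seed(42)
  items <- c("fever", "cough", "rash")
  for (rep in 1:300) {
    p <- random_predicate(items)
    r <- random_responses(items)
    expect_identical(eval_predicate(p, r), naive_eval(p, r))
  }
})

test_that("missing-as-absent: blanking an absent item never flips", {
  set.seed(43)
  items <- c("fever", "cough", "rash")
  for (rep in 1:200) {
    p <- random_predicate(items)
    r <- random_responses(items)
    before <- eval_predicate(p, r)
    absent <- names(Filter(function(v) !is.na(v) && identical(v, "no"), r))
    for (it in absent) {
      r2 <- r
      r2[[it]] <- NA_character_
      expect_identical(eval_predicate(p, r2), before)
    }
  }
})

test_that("none_of is the negation of any_of on random records", {
  set.seed(44)
  items <- c("fever", "cough", "rash")
  for (rep in 1:200) {
    kids <- lapply(1:2, function(i) random_predicate(items, depth = 2))
    r <- random_responses(items)
    expect_identical(eval_predicate(do.call(p_none, kids), r),
                     !eval_predicate(do.call(p_any, kids), r))
  }
})

test_that("AIDS screen implements the five published conditions", {
  defs <- builtin_definitions()
  aids <- defs$aids
  fire <- function(...) evaluate_definition(aids, list(...))
  # (1) jaundice alone
  expect_true(fire(jaundice = "yes"))
  # (2) chronic diarrhea > 1 month: 45 d fires, 30 d does not
  expect_true(fire(loose_stools = "yes", diarrhea_duration_days = 45))
  expect_false(fire(loose_stools = "yes", diarrhea_duration_days = 30))
  # (3) chronic fever > 1 month
  expect_true(fire(fever = "yes", fever_duration_days = 40))
  expect_false(fire(fever = "yes", fever_duration_days = 20))
  # (4) wasting: at least one of four signs
  for (it in c("paleness", "hair_color_change", "edema_legs",
               "dry_scaly_skin")) {
    expect_true(evaluate_definition(aids, setNames(list("yes"), it)))
  }
  # (5) cough/trouble breathing 3-27 d with fever, no recent TB
  expect_true(fire(cough = "yes", cough_duration_days = 10, fever = "yes"))
  expect_false(fire(cough = "yes", cough_duration_days = 28,
                    fever = "yes")) # outside the window
  expect_false(fire(cough = "yes", cough_duration_days = 2,
                    fever = "yes"))
  expect_false(fire(cough = "yes", cough_duration_days = 10, fever = "yes",
                    tb_diagnosis_recent = "yes")) # recent TB blocks it
  # all five component groups absent
  expect_false(fire(fever = "no"))
})

test_that("diarrhea screen needs loose stools AND >= 6 stools/day", {
  defs <- builtin_definitions()
  d <- defs$diarrhea
  expect_true(evaluate_definition(d, list(loose_stools = "yes",
                                          stools_per_day = 6)))
  expect_false(evaluate_definition(d, list(loose_stools = "yes",
                                           stools_per_day = 4)))
  expect_false(evaluate_definition(d, list(stools_per_day = 9)))
  # symptom-only variant used for data-quality probes
  d2 <- builtin_definitions(va_parameters(diarrhea_symptom_only = TRUE))
  expect_true(evaluate_definition(d2$diarrhea, list(loose_stools = "yes")))
})

test_that("definitions reference only codebook items, checked at load", {
  cb <- tiny_codebook()
  bad <- case_definition("x", p_item_equals("not_an_item"), "child")
  expect_error(validate_predicate(bad$predicate, cb), "not_an_item")
  # kind mismatch caught too
  expect_error(validate_predicate(p_item_at_least("fever", 2), cb),
               "incompatible")
})

test_that("definition config: YAML round trip and override semantics", {
  cb <- builtin_codebook()
  defs <- builtin_definitions()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_definitions(defs, path)
  expect_equal(load_definitions(path, cb), defs, ignore_attr = "parameters")

  # empty config = builtin defaults
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("parameters: {}", empty)
  expect_equal(load_definitions(empty, cb), defs)

  # parameter override changes only the stool threshold
  ov <- withr::local_tempfile(fileext = ".yaml")
  writeLines("parameters:\n  min_stools_per_day: 4", ov)
  defs4 <- load_definitions(ov, cb)
  expect_true(evaluate_definition(defs4$diarrhea,
                                  list(loose_stools = "yes",
                                       stools_per_day = 4)))
  same <- setdiff(names(defs), "diarrhea")
  expect_equal(defs4[same], defs[same], ignore_attr = TRUE)

  # unknown cause label rejected
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0("definitions:\n- cause: dragonpox\n  strata: [child]\n",
                    "  predicate:\n    item_equals: {item: fever}"), bad)
  expect_error(load_definitions(bad, cb), "dragonpox")

  # unknown item inside a predicate rejected with location
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0("definitions:\n- cause: malaria\n  strata: [child]\n",
                    "  predicate:\n    item_equals: {item: wingbeats}"),
             bad2)
  expect_error(load_definitions(bad2, cb), "wingbeats")
})
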