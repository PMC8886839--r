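test_that("default configuration matches the adopted seven-criterion tool", {
  cfg <- default_config()
  expect_length(cfg$criteria, 7)
  w <- sapply(cfg$criteria, `[[`, "weight")
  names(w) <- sapply(cfg$criteria, `[[`, "id")
  expect_equal(sum(w), 100, tolerance = 1e-12)
  expect_equal(max(w), 23.49)
  expect_equal(min(w), 8.67)
  expect_equal(w[names(published_weights)], published_weights,
               ignore_attr = FALSE)
  expect_equal(cfg$threshold, 65)
  # rank order follows the consensus ranking
  ord <- order(sapply(cfg$criteria, `[[`, "rank"))
  expect_equal(sapply(cfg$criteria, `[[`, "id")[ord],
               names(published_weights))
  # pharmacovigilance is the single external-score criterion
  ext <- sapply(cfg$criteria, `[[`, "external_score")
  expect_equal(sapply(cfg$criteria, `[[`, "id")[ext], "pharmacovigilance")
  expect_length(cfg$criteria[ext][[1]]$options, 0)
  # the three hard exclusion triggers are present, with zero fractions
  triggers <- unlist(lapply(cfg$criteria, function(cr) {
    vapply(Filter(function(o) o$exclusion_trigger, cr$options),
           `[[`, character(1), "label")
  }))
  expect_setequal(triggers, c("not marketed in the country of origin",
                              "no GMP certificate", "less than 25%"))
  expect_equal(nrow(validate_config(cfg)), 0)
})

test_that("structural invariants are enforced with field paths", {
  expect_error(scoring_option("bad", 1.2), class = "mcda_validation_error")
  expect_error(scoring_option("trigger with score", 0.5, exclusion_trigger = TRUE),
               class = "mcda_validation_error")
  ok <- function(id, rank, weight = 50) {
    criterion(id, id, rank, weight,
              list(scoring_option("yes", 1), scoring_option("no", 0)))
  }
  # duplicate ranks
  expect_error(tool_config(list(ok("a", 3), ok("b", 3))),
               class = "mcda_validation_error")
  # weights off 100 beyond tolerance
  expect_error(tool_config(list(ok("a", 1, 50), ok("b", 2, 49)),
                           weight_tolerance = 0.01),
               class = "mcda_validation_error")
  # external criterion with options / scored criterion with < 2 options
  expect_error(criterion("x", "x", 1, 10, list(scoring_option("one", 1)),
                         external_score = TRUE),
               class = "mcda_validation_error")
  expect_error(criterion("x", "x", 1, 10, list(scoring_option("one", 1))),
               class = "mcda_validation_error")
  # threshold bounds
  expect_error(tool_config(list(ok("a", 1), ok("b", 2, 50)), threshold = 0),
               class = "mcda_validation_error")
  # violation records carry the offending field path
  cfg <- default_config()
  cfg$criteria[[1]]$weight <- -1
  v <- validate_config(cfg)
  expect_true(any(grepl("reference_country_use.weight", v$field, fixed = TRUE)))
})

test_that("config serialization round-trips exactly and deterministically", {
  cfg <- default_config()
  expect_identical(load_config(save_config(cfg)), cfg)
  expect_identical(save_config(cfg), save_config(cfg))
  # file round-trip, including unicode labels
  cfg$criteria[[7]]$name <- "Macroeconomic benefit — local manufacturing (مصر)"
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  expect_identical(load_config(path), cfg)
})

test_that("random configurations survive the save/load round-trip", {
  set.seed(42)
  for (i in 1:20) {
    cfg <- random_config(with_external = i %% 2 == 0, with_triggers = TRUE)
    expect_identical(load_config(save_config(cfg)), cfg)
  }
})

test_that("loading rejects invalid or malformed configs", {
  expect_error(load_config("criteria: ["), class = "mcda_schema_error")
  cfg <- default_config()
  bad <- cfg
  bad$criteria[[1]]$weight <- bad$criteria[[1]]$weight - 1
  txt <- yaml::as.yaml(tendermcda:::config_to_list(bad))
  expect_error(load_config(txt), class = "mcda_validation_error")
  bad2 <- cfg
  bad2$criteria[[2]]$rank <- 3L
  txt2 <- yaml::as.yaml(tendermcda:::config_to_list(bad2))
  expect_error(load_config(txt2), regexp = "permutation",
               class = "mcda_validation_error")
})

test_that("the documented workshop sequence reduces 13 criteria to 7", {
  cfg <- primary_config()
  expect_length(cfg$criteria, 13)
  mods <- workshop_modifications()
  expect_length(mods, 6)
  for (m in mods) cfg <- apply_modification(cfg, m)
  expect_length(cfg$criteria, 7)
  expect_true(cfg$weights_stale)
  expect_setequal(sapply(cfg$criteria, `[[`, "id"), names(published_weights))
  expect_equal(sort(sapply(cfg$criteria, `[[`, "rank")), 1:7)
  # the merged criterion replaces the two quality criteria
  expect_true("manufacturing_quality" %in% sapply(cfg$criteria, `[[`, "id"))
  expect_false(any(c("api_manufacturing_quality", "finished_product_quality")
                   %in% sapply(cfg$criteria, `[[`, "id")))
})

test_that("modifications compact ranks and never renormalize weights", {
  two <- tool_config(list(
    criterion("a", "A", 1, 60, list(scoring_option("y", 1), scoring_option("n", 0))),
    criterion("b", "B", 2, 40, list(scoring_option("y", 1), scoring_option("n", 0)))
  ))
  one <- apply_modification(two, modification("exclude", "b"))
  expect_length(one$criteria, 1)
  expect_equal(one$criteria[[1]]$rank, 1L)
  expect_equal(one$criteria[[1]]$weight, 60)  # untouched, flagged stale
  expect_true(one$weights_stale)
  expect_error(apply_modification(two, modification("exclude", "zzz")),
               class = "mcda_unknown_id")
  expect_error(apply_modification(one, modification("exclude", "a")),
               class = "mcda_validation_error")

  # merge of ranks 2 and 5 in a 5-criterion config: replacement lands at 2
  cfg5 <- tool_config(lapply(1:5, function(i) {
    criterion(paste0("c", i), paste0("C", i), i, 20,
              list(scoring_option("y", 1), scoring_option("n", 0)))
  }))
  merged <- apply_modification(
    cfg5,
    modification("merge", c("c2", "c5"),
                 replacement = criterion("c25", "C2+C5", 2, 0,
                                         list(scoring_option("y", 1),
                                              scoring_option("n", 0)))))
  expect_length(merged$criteria, 4)
  expect_equal(sort(sapply(merged$criteria, `[[`, "rank")), 1:4)
  ranks <- sapply(merged$criteria, `[[`, "rank")
  ids <- sapply(merged$criteria, `[[`, "id")
  expect_equal(ids[ranks == 2], "c25")
})

test_that("random modification sequences preserve the rank permutation", {
  set.seed(7)
  for (rep in 1:10) {
    cfg <- random_config(K = 5)
    for (step in 1:3) {
      ids <- sapply(cfg$criteria, `[[`, "id")
      if (length(ids) > 2 && runif(1) < 0.5) {
        cfg <- apply_modification(cfg, modification("exclude", sample(ids, 1)))
      } else if (length(ids) >= 2) {
        pair <- sample(ids, 2)
        repl <- criterion(paste0("m", rep, step), "merged", 1, 0,
                          list(scoring_option("y", 1), scoring_option("n", 0)))
        cfg <- apply_modification(cfg, modification("merge", pair, repl))
      }
      ranks <- sapply(cfg$criteria, `[[`, "rank")
      expect_equal(sort(ranks), seq_along(ranks))
    }
  }
})

test_that("display rounding preserves the printed sum of 100", {
  w <- c(100 / 3, 100 / 3, 100 / 3)
  d <- display_weights(w)
  expect_equal(sum(d), 100)
  expect_true(all(abs(d - w) <= 0.01))
  set.seed(11)
  for (i in 1:25) {
    raw <- runif(sample(3:9, 1))
    w <- 100 * raw / sum(raw)
    d <- display_weights(w)
    expect_equal(sum(d), 100)
    expect_true(all(abs(d - w) < 0.01 + 1e-12))
  }
})
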