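test_that("delay-to-distance recoding is the documented bijection", {
  expect_equal(recode_distance("IN", "T1"), "D1")
  expect_equal(recode_distance("OUT", "T1"), "D5")
  expect_equal(recode_distance("IN", "T3"), "D3")
  expect_equal(recode_distance("OUT", "T5"), "D1")

  # bijection per direction
  for (dir in c("IN", "OUT")) {
    out <- recode_distance(rep(dir, 5), paste0("T", 1:5))
    expect_setequal(out, paste0("D", 1:5))
  }
  # flipping the direction reverses the order
  expect_equal(recode_distance(rep("IN", 5), paste0("T", 1:5)),
               rev(recode_distance(rep("OUT", 5), paste0("T", 1:5))))
  expect_error(recode_distance("UP", "T1"), "direction")
  expect_error(recode_distance("IN", "T9"), "delay")
})

make_trials <- function(rts, subject = "S01", condition = "synchronous",
                        session = "before", direction = "IN", delay = "T1") {
  data.frame(subject = subject, condition = condition, session = session,
             direction = direction, delay = delay, rt = rts, catch = FALSE)
}

test_that("two-SD trimming removes exactly the constructed outlier", {
  # cell of 19 trials at 400 ms and one at 900 ms:
  rts <- c(rep(400, 19), 900)
  # arithmetic check of the rule on this cell
  expect_gt(abs(900 - mean(rts)), 2 * sd(rts))
  expect_lt(abs(400 - mean(rts)), 2 * sd(rts))

  tr <- trim_outliers(validate_trials(make_trials(rts)))
  expect_equal(nrow(tr$trials), 19)
  expect_true(all(tr$trials$rt == 400))
  expect_equal(tr$report$removed, 1)
  expect_equal(tr$report$n, 20)
})

test_that("trimming degenerate cells is a no-op", {
  tr <- trim_outliers(validate_trials(make_trials(rep(412, 10))))
  expect_equal(nrow(tr$trials), 10)   # sd = 0: nothing trimmed
  empty <- trim_outliers(make_trials(400)[0, ])
  expect_equal(nrow(empty$trials), 0)
  expect_equal(sum(empty$report$removed), 0)
})

test_that("summaries average subjects, not trials", {
  # subject A has 4 trials at 400, subject B has 1 trial at 500:
  # balanced aggregation gives 450, trial-pooling would give 420
  d <- rbind(make_trials(rep(400, 4), subject = "A"),
             make_trials(500, subject = "B"))
  s <- summarize_rt(validate_trials(d))
  expect_equal(s$mean, 450)
  expect_equal(s$n_subjects, 2)
  expect_equal(s$sem, sd(c(400, 500)) / sqrt(2))

  solo <- summarize_rt(validate_trials(make_trials(c(400, 420))))
  expect_true(is.na(solo$sem))   # single subject: SEM undefined
})

test_that("the strict trial reader validates labels and round-trips", {
  d <- generate_rt_dataset(synthetic_rt_spec(n_subjects = 2,
                                             trials_per_cell = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(d[names(d) != "distance"], path)
  d2 <- read_trials(path)
  expect_equal(nrow(d2), nrow(d))
  expect_true(all(d2$distance %in% paste0("D", 1:5)))

  bad <- d; bad$delay[1] <- "T7"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(bad[names(bad) != "distance"], path2)
  expect_error(read_trials(path2), "delay")

  bad2 <- d; bad2$rt[which(bad2$catch)[1]] <- 400
  expect_error(validate_trials(bad2[names(bad2) != "distance"]), "catch")
  expect_error(read_trials(withr::local_tempfile(fileext = ".tsv")), "file")
})

test_that("per-session boundary fits reproduce the group-mean fit", {
  # trials whose subject means equal the published before-training values
  means <- c(517, 497, 464, 459, 455)
  rows <- list()
  for (s in 1:4) for (k in 1:5)
    rows[[length(rows) + 1]] <- make_trials(rep(means[k], 3),
                                            subject = sprintf("S%02d", s),
                                            delay = paste0("T", k))
  trials <- validate_trials(do.call(rbind, rows))
  fits <- boundary_per_session(trials, "synchronous")
  expect_named(fits, "before")
  # identical to fitting the five means directly (frozen oracle value)
  expect_equal(unname(fits$before$coef["xc"]), 912.91, tolerance = 1e-2)

  # after-training fixture: published D2-D5 means plus a synthetic D1 value
  means_after <- c(500, 470, 450, 439, 439)  # D1 unpublished, set to 500
  rows <- list()
  for (s in 1:4) for (k in 1:5) {
    rows[[length(rows) + 1]] <- make_trials(rep(means[k], 3),
                                            subject = sprintf("S%02d", s),
                                            delay = paste0("T", k))
    rows[[length(rows) + 1]] <- make_trials(rep(means_after[k], 3),
                                            subject = sprintf("S%02d", s),
                                            session = "after1",
                                            delay = paste0("T", k))
  }
  trials2 <- validate_trials(do.call(rbind, rows))
  fits2 <- boundary_per_session(trials2, "synchronous")
  # the boundary moves to an earlier touch delay (farther from the body)
  expect_lt(fits2$after$coef["xc"], fits2$before$coef["xc"])

  expect_error(boundary_per_session(trials[trials$direction == "OUT", ],
                                    "synchronous"), "IN")
})

test_that("the pipeline is deterministic on identical inputs", {
  set.seed(77)
  d <- generate_rt_dataset(synthetic_rt_spec(n_subjects = 4,
                                             trials_per_cell = 3))
  s1 <- summarize_rt(trim_outliers(d)$trials)
  s2 <- summarize_rt(trim_outliers(d)$trials)
  expect_identical(s1, s2)
})
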