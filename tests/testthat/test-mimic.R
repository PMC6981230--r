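test_that("exclusion rules remove in-stay deaths, minors and unreadmitted deaths", {
  fx <- mimic_fixture()
  out <- apply_exclusions(fx$ICUSTAYS, fx$PATIENTS)
  expect_setequal(out$ICUSTAY_ID, c(1001L, 1002L, 1003L, 5001L))
  ex <- attr(out, "exclusions")
  expect_equal(unname(ex["died_in_stay"]), 1)
  expect_equal(unname(ex["under_18"]), 1)
  expect_equal(unname(ex["death_30d_no_readmit"]), 2)
  # a missing discharge timestamp is rejected with a logged reason
  fx2 <- fx
  fx2$ICUSTAYS$OUTTIME[1] <- NA
  out2 <- apply_exclusions(fx2$ICUSTAYS, fx2$PATIENTS)
  expect_false(1001L %in% out2$ICUSTAY_ID)
  expect_true(any(attr(out2, "log")$reason == "missing discharge timestamp"))
})

test_that("30-day readmission labelling is inclusive at the boundary", {
  # stays of 1 day each, separated by the given gaps (in days)
  mk <- function(gaps_days) {
    n <- length(gaps_days) + 1
    stays <- data.frame(ICUSTAY_ID = integer(0), INTIME = ts(character(0)),
                        OUTTIME = ts(character(0)))
    cur_in <- ts("2130-01-01 00:00:00")
    for (i in seq_len(n)) {
      cur_out <- cur_in + 86400
      stays <- rbind(stays, data.frame(ICUSTAY_ID = i, INTIME = cur_in,
                                       OUTTIME = cur_out))
      if (i <= length(gaps_days)) cur_in <- cur_out + gaps_days[i] * 86400
    }
    stays
  }
  expect_equal(label_readmission(mk(29.5)), c(1L, 0L))
  expect_equal(label_readmission(mk(31)), c(0L, 0L))
  expect_equal(label_readmission(mk(30)), c(1L, 0L))      # inclusive boundary
  expect_equal(label_readmission(mk(c(10, 40))), c(1L, 0L, 0L))
  ov <- mk(5)
  ov$INTIME[2] <- ov$OUTTIME[1] - 3600                    # overlap
  expect_error(label_readmission(ov), "overlapping.*1/2")
})

test_that("OASIS vital bins reproduce the published cut-points", {
  expect_equal(oasis_bin_vital("temp", 35.0), "temp:33.22-35.93")
  expect_equal(oasis_bin_vital("map", 55), "map:51-61.32")
  expect_equal(oasis_bin_vital("map", 61.32), "map:51-61.32")
  expect_equal(oasis_bin_vital("resp_rate", 35), "resp_rate:31-44")
  expect_equal(oasis_bin_vital("resp_rate", 44), "resp_rate:31-44")
  expect_equal(oasis_bin_vital("heart_rate", c(30, 88, 89, 130)),
               c("heart_rate:lt33", "heart_rate:33-88", "heart_rate:89-106",
                 "heart_rate:gt125"))
  expect_equal(oasis_bin_vital("gcs", c(3, 13, 14, 15)),
               c("gcs:3-7", "gcs:8-13", "gcs:14", "gcs:15"))
  expect_equal(oasis_bin_vital("ventilated", c(1, 0)),
               c("ventilated:yes", "ventilated:no"))
  # out-of-physiological-range values are flagged as NA
  expect_true(is.na(oasis_bin_vital("temp", 80)))
  expect_true(is.na(oasis_bin_vital("heart_rate", -5)))
  expect_true(is.na(oasis_bin_vital("temp", 30, bounds = c(32, 45))))
  expect_error(oasis_bin_vital("blood_sugar", 5), "unknown vital")
  expect_length(oasis_vital_codes(), 33)
})

test_that("consecutive-duplicate removal keeps the latest of each run", {
  ev <- data.frame(code = c("A", "A", "B"), time = 1:3)
  expect_equal(dedupe_consecutive(ev)$time, c(2, 3))
  ev2 <- data.frame(code = c("A", "B", "A"), time = 1:3)
  expect_equal(dedupe_consecutive(ev2), ev2)
  # non-vital occurrences are untouched and break runs: the middle "A" is
  # not a vital, so the first vital "A" has no identical vital successor
  ev3 <- data.frame(code = c("A", "A", "A"), time = 1:3)
  expect_equal(dedupe_consecutive(ev3, is_vital = c(TRUE, FALSE, TRUE))$time,
               1:3)
})

test_that("dedupe matches a brute-force run-length scan on random sequences", {
  brute <- function(codes) {
    keep <- rep(TRUE, length(codes))
    for (i in seq_along(codes)[-length(codes)]) {
      if (codes[i + 1] == codes[i]) keep[i] <- FALSE
    }
    keep
  }
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    ev <- data.frame(code = sample(letters[1:4], n, replace = TRUE),
                     time = seq_len(n))
    got <- dedupe_consecutive(ev)
    expect_equal(got$time, which(brute(ev$code)))
  }
})

test_that("rare categories are relabelled strictly below the stay threshold", {
  # value x in 99 stays -> other; value y in 100 stays -> kept
  vals <- c(rep("x", 99), rep("y", 100), rep("z", 3))
  stays <- c(sprintf("sx%03d", 1:99), sprintf("sy%03d", 1:100),
             c("sz1", "sz1", "sz2"))
  rl <- relabel_rare(vals, stays, threshold = 100)
  expect_true(all(rl$mapped[vals == "x"] == "other"))
  expect_true(all(rl$mapped[vals == "y"] == "y"))
  expect_true(all(rl$mapped[vals == "z"] == "other"))
  expect_setequal(rl$vocab$value, c("y", "other"))
  expect_equal(rl$vocab$index, seq_len(nrow(rl$vocab)))
  # brute-force comparison on random tables
  set.seed(15)
  for (rep in 1:10) {
    v <- sample(letters[1:6], 300, replace = TRUE)
    s <- sample(sprintf("s%02d", 1:40), 300, replace = TRUE)
    thr <- sample(3:12, 1)
    rl2 <- relabel_rare(v, s, thr)
    for (lv in unique(v)) {
      n_stays <- length(unique(s[v == lv]))
      expect_equal(unique(rl2$mapped[v == lv]),
                   if (n_stays < thr) "other" else lv)
    }
  }
})

test_that("elapsed times are computed in the right units and clamped", {
  ref <- ts("2130-01-10 12:00:00")
  expect_equal(elapsed_time(ref, ref, "days"), 0)
  expect_equal(elapsed_time(ts("2129-01-10 12:00:00"), ref, "days"), 365)
  expect_equal(elapsed_time(ts("2130-01-10 06:30:00"), ref, "hours"), 5.5)
  expect_warning(el <- elapsed_time(ref + 3600, ref, "hours"), "clamped")
  expect_equal(el, 0)
})

test_that("the full extractor produces a labelled, split, indexed cohort", {
  fx <- mimic_fixture()
  co <- extract_mimic_cohort(fx, threshold = 1, test_fraction = 0.25, seed = 3)
  expect_s3_class(co, "emr_cohort")
  expect_setequal(co$stays$stay_id, c("1001", "1002", "1003", "5001"))
  lab <- setNames(co$stays$label, co$stays$stay_id)
  # 1002 -> 1003 within 10 days; 5001 readmitted (excluded stay still counts)
  expect_equal(unname(lab[c("1001", "1002", "1003", "5001")]), c(0L, 1L, 0L, 1L))
  # every event code exists in the vocabulary
  for (s in c("dxproc", "medvit")) {
    expect_true(all(co$events[[s]]$code %in% co$vocab[[s]]$index))
    expect_true(all(co$events[[s]]$elapsed >= 0))
  }
  # dx codes from earlier admissions carry day-scale elapsed times;
  # index-admission codes are available at discharge (elapsed 0)
  dx <- merge(co$events$dxproc, co$vocab$dxproc, by.x = "code", by.y = "index")
  hist_dx <- dx[dx$stay_id == "1002" & dx$name == "dx:4280", ]
  expect_true(any(hist_dx$elapsed == 0))        # recorded again at 102
  idx_dx <- dx[dx$stay_id == "1001", ]
  expect_true(all(idx_dx$elapsed == 0))
  # statics: encoded matrix has the schema width and plausible values
  expect_equal(ncol(co$X), 23)
  expect_true(all(co$stays$age >= 18))
  # med/vit events are hour-scale within the stay (< 10 days * 24)
  expect_true(all(co$events$medvit$elapsed <= 240))
  # patient-level split; deterministic rerun
  tab <- table(co$stays$patient_id, co$stays$split)
  expect_true(all(rowSums(tab > 0) == 1))
  co2 <- extract_mimic_cohort(fx, threshold = 1, test_fraction = 0.25, seed = 3)
  expect_identical(co$stays, co2$stays)
  expect_identical(co$events, co2$events)
  # rare-value threshold folds everything into "other"
  co3 <- extract_mimic_cohort(fx, threshold = 10, test_fraction = 0.25, seed = 3)
  expect_true(all(co3$vocab$dxproc$name == "other"))
})

test_that("vital-sign extraction bins, dedupes and converts units", {
  fx <- mimic_fixture()
  co <- extract_mimic_cohort(fx, threshold = 1, test_fraction = 0.25, seed = 3)
  mv <- merge(co$events$medvit, co$vocab$medvit, by.x = "code", by.y = "index")
  s1 <- mv[mv$stay_id == "1001", ]
  # two consecutive identical heart-rate bins collapse to the latest
  expect_equal(sum(s1$name == "vit:heart_rate:89-106"), 1)
  expect_true("vit:resp_rate:31-44" %in% s1$name)
  expect_true("vit:temp:33.22-35.93" %in% s1$name)
  expect_true("vit:urine_output:lt671" %in% s1$name)
  expect_true("med:furosemide" %in% s1$name)
  # vital_group recorded for baseline feature construction
  expect_true(all(!is.na(mv$vital_group[mv$kind == "vit"])))
})
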