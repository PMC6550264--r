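header <- "patient_id,provider_code,event_date,setting,lsoa_code"

test_that("reader validates the schema and keeps well-formed rows", {
  p0 <- write_log_csv(header)
  expect_equal(nrow(read_event_log(p0)), 0L)

  p1 <- write_log_csv(c("setting,provider_code,patient_id,event_date,lsoa_code",
                        "AE,RAA,P1,2014-01-01,E01",
                        "IP,RAA,P1,2014-01-02,E01",
                        "OP,RAB,P2,2014-01-03,E01"))
  log <- read_event_log(p1)   # column order is free
  expect_equal(nrow(log), 3L)
  expect_setequal(log$setting, c("AE", "IP", "OP"))
  expect_s3_class(log$event_date, "Date")

  expect_error(read_event_log(write_log_csv("patient_id,provider_code,event_date")),
               class = "carefrag_schema_error")
})

test_that("invalid rows are dropped and counted, or fail fast when strict", {
  rows <- c(header,
            sprintf("P%02d,RAA,2014-01-%02d,OP,E01", 1:8, 1:8),
            "P09,,2014-01-09,OP,E01",
            ",RAB,2014-01-10,OP,E01")
  log <- read_event_log(write_log_csv(rows))
  expect_equal(nrow(log), 8L)
  expect_equal(attr(log, "provenance")$n_dropped_missing_id, 2L)

  bad <- c(header, "P1,RAA,2014-01-01,OP,E01", "P2,RAB,not-a-date,OP,E01",
           "P3,RAC,2014-01-03,XX,E01")
  log2 <- read_event_log(write_log_csv(bad))
  expect_equal(nrow(log2), 1L)
  prov <- attr(log2, "provenance")
  expect_equal(prov$n_dropped_bad_date, 1L)
  expect_equal(prov$n_dropped_bad_setting, 1L)
  expect_error(read_event_log(write_log_csv(bad), strict = TRUE),
               class = "carefrag_row_error")
})

test_that("merge map canonicalises providers without changing event counts", {
  log <- make_log(rep("P1", 9), rep(c("A", "B", "C"), 3), 1:9)
  expect_identical(apply_merge_map(log, c(A = "A"))$provider_code, log$provider_code)
  m1 <- apply_merge_map(log, c(B = "A"))
  expect_setequal(unique(m1$provider_code), c("A", "C"))
  m2 <- apply_merge_map(log, c(B = "A", C = "A"))
  expect_equal(nrow(m2), 9L)
  expect_equal(unique(m2$provider_code), "A")
  expect_error(apply_merge_map(log, c(B = "A", A = "C")),
               class = "carefrag_invalid_map")
})

test_that("patient window keeps events up to an inclusive 365-day boundary", {
  log <- make_log(c("P1", "P1", "P2", "P2"), "A", c(0, 400, 0, 365))
  w <- apply_patient_window(log)
  expect_equal(w[patient_id == "P1", .N], 1L)   # day 400 outside
  expect_equal(w[patient_id == "P2", .N], 2L)   # day 365 on the boundary
  # hand-enumerated mixed spans; first event never dropped
  log2 <- make_log(rep(c("Q1", "Q2", "Q3", "Q4"), each = 3), "A",
                   c(0, 100, 370, 5, 360, 366, 0, 365, 366, 50, 51, 52))
  w2 <- apply_patient_window(log2)
  # Q1: 370 > 365; Q2: window starts at day 5 so 366 is inside; Q3: 366 out
  expect_equal(w2[, .N, keyby = patient_id]$N, c(2L, 3L, 2L, 3L))
  expect_true(all(log2[, min(event_date), by = patient_id]$V1 %in% w2$event_date))
})

test_that("canonical sort is a deterministic total order with AE<IP<OP ties", {
  log <- make_log(c("P1", "P1"), c("A", "A"), c(0, 0), setting = c("OP", "AE"))
  expect_equal(canonical_sort(log)$setting, c("AE", "OP"))
  log2 <- make_log(c("P1", "P1"), c("ZZZ", "AAA"), c(0, 0), setting = "IP")
  expect_equal(canonical_sort(log2)$provider_code, c("AAA", "ZZZ"))
  # shuffling the input never changes the sorted output; sorting is idempotent
  big <- generate_event_log(simulation_config(n_patients = 50, allow_same_day = TRUE,
                                              date_span_days = 5, seed = 4))$events
  sorted <- canonical_sort(big)
  expect_equal(canonical_sort(sorted), sorted, ignore_attr = TRUE)
  for (s in 1:3) {
    set.seed(s)
    shuffled <- big[sample(.N)]
    expect_equal(canonical_sort(shuffled), sorted, ignore_attr = TRUE)
  }
})
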