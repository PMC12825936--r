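test_that("delimited tables load and attach child rows by primaryid", {
  dir <- withr::local_tempdir()
  demo <- mk_demo(1:3)
  reac <- tibble::tibble(primaryid = c(1, 1, 2, 3, 3),
                         pt = c("nausea", "cardiotoxicity", "fatigue",
                                "nausea", "diarrhoea"))
  readr::write_delim(demo, file.path(dir, "demo.txt"), delim = "$", na = "")
  readr::write_delim(reac, file.path(dir, "reac.txt"), delim = "$", na = "")
  store <- read_faers_tables(demo = file.path(dir, "demo.txt"),
                             reac = file.path(dir, "reac.txt"))
  expect_s3_class(store, "faers_store")
  expect_equal(nrow(store$demo), 3)
  expect_equal(nrow(store$reac), 5)
  expect_error(read_faers_tables(demo = file.path(dir, "nope.txt")),
               "DEMO")
})

test_that("empty reaction tables and duplicated primaryids are handled", {
  dir <- withr::local_tempdir()
  demo <- mk_demo(c(1, 2, 2))
  readr::write_delim(demo, file.path(dir, "demo.txt"), delim = "$", na = "")
  readr::write_delim(tibble::tibble(primaryid = integer(), pt = character()),
                     file.path(dir, "reac.txt"), delim = "$", na = "")
  w <- capture_warnings(
    store <- read_faers_tables(demo = file.path(dir, "demo.txt"),
                               reac = file.path(dir, "reac.txt"))
  )
  expect_match(w, "duplicated primaryid", all = FALSE)
  expect_match(w, "no usable rows", all = FALSE)
  expect_equal(nrow(store$demo), 2)
  expect_equal(attr(store, "load_log")$demo_duplicate_primaryid, 1)
  expect_equal(nrow(store$reac), 0)
})

test_that("deduplication retains latest fda_dt, then highest primaryid", {
  demo <- mk_demo(primaryid = c(100, 101, 200, 201),
                  caseid = c(7, 7, 9, 9),
                  fda_dt = c("20230101", "20230401", "20230401", "20230401"),
                  event_dt = c("20221201", "20221201", "20220601", "20220615"))
  store <- faers_deduplicate(mk_store(demo))
  expect_setequal(store$demo$primaryid, c(101, 201))
  expect_equal(store$demo$caseid, c(7, 9))
})

test_that("partial fda_dt values are padded for ordering only", {
  demo <- mk_demo(primaryid = c(1, 2, 3), caseid = c(5, 5, 5),
                  fda_dt = c("2023", "202302", "20230101"),
                  event_dt = c("20220101", "20220201", "20220301"))
  store <- faers_deduplicate(mk_store(demo))
  # 202302 pads to 20230201, the latest of the three keys
  expect_equal(store$demo$primaryid, 2)
})

test_that("cross-field screen removes identical reports across caseids", {
  demo <- mk_demo(primaryid = c(10, 20, 30), caseid = c(1, 2, 3),
                  fda_dt = "20230301",
                  event_dt = c("20230101", "20230101", "20230201"))
  reac <- tibble::tibble(primaryid = c(10, 20, 30), pt = "nausea")
  store <- faers_deduplicate(mk_store(demo, reac = reac))
  # reports 10 and 20 are identical on every screened field: keep 20
  expect_setequal(store$demo$primaryid, c(20, 30))
  expect_equal(attr(store, "dedup_log")$crossfield_removed, 1)
})

test_that("deduplication is idempotent and shrinks caseids to a unique subset", {
  sim <- simulate_reports(sim_config(n_reports = 400, seed = 11,
                                     duplicate_rate = 0.3,
                                     crossdup_rate = 0.02))
  store <- as_faers_store(sim$tables)
  d1 <- faers_deduplicate(store)
  d2 <- faers_deduplicate(d1)
  expect_identical(d1$demo, d2$demo)
  expect_identical(d1$reac, d2$reac)
  expect_false(anyDuplicated(d1$demo$caseid) > 0)
  expect_true(all(d1$demo$caseid %in% store$demo$caseid))
})

test_that("primary-suspect filter follows role codes and is monotone", {
  demo <- mk_demo(1:4)
  drug <- tibble::tibble(
    primaryid = c(1, 2, 3, 3, 4),
    drugname = c("Enhertu", "enhertu", "padcev", "trodelvy", "aspirin"),
    role_cod = c("PS", "C", "SS", "PS", "PS")
  )
  store <- mk_store(demo, drug = drug)
  kept <- filter_primary_suspect(store, c("enhertu", "padcev", "trodelvy"))
  # 1: PS match (case-insensitive); 2: concomitant only; 3: any-PS rule
  expect_setequal(kept$demo$primaryid, c(1, 3))
  expect_error(filter_primary_suspect(store, character(0)), "at least one")

  f1 <- filter_primary_suspect(store, "enhertu")$demo$primaryid
  f2 <- filter_primary_suspect(store, "trodelvy")$demo$primaryid
  f12 <- filter_primary_suspect(store, c("enhertu", "trodelvy"))$demo$primaryid
  expect_true(all(f1 %in% f12) && all(f2 %in% f12))
})

test_that("cardiac tagging flags reports via the SOC map without changing counts", {
  demo <- mk_demo(1:3)
  reac <- tibble::tibble(primaryid = c(1, 1, 2, 2),
                         pt = c("Cardiotoxicity", "nausea", "nausea",
                                "mystery term"))
  store <- tag_cardiac(mk_store(demo, reac = reac), test_term_map())
  expect_equal(nrow(store$demo), 3)
  expect_equal(store$demo$has_cardiac, c(TRUE, FALSE, FALSE))
  expect_equal(store$demo$n_cardiac_reactions, c(1L, 0L, 0L))
  # unknown PTs stay in the reaction list but are never cardiac
  expect_equal(attr(store, "unknown_pt_log")$unknown_pts, "mystery term")
  expect_equal(nrow(store$reac), 4)
})

test_that("flattening picks the most severe outcome and flags fatality", {
  demo <- mk_demo(1:2)
  outc <- tibble::tibble(primaryid = c(1, 1, 2), outc_cod = c("OT", "DE", "HO"))
  flat <- flatten_reports(mk_store(demo, outc = outc))
  expect_equal(flat$outcome, c("DE", "HO"))
  expect_equal(flat$fatal, c(TRUE, FALSE))
})
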