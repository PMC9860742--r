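test_that("reading preserves fields, treats the header as metadata, and keeps row order", {
  tab <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                             "A,male,60s,2015",
                             "B,,50s,2016"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$case_id, c("A", "B"))
  expect_identical(tab$sex[2L], "")          # empty string is the missing marker
  expect_identical(attr(tab, "table_kind"), "demo")
})

test_that("a missing required column raises a schema error naming it", {
  err <- expect_error(
    read_tiny("demo", c("case_id,age,reporting_year", "A,60s,2015")),
    "sex")
  expect_s3_class(err, "pvsignal_schema_error")
  expect_error(read_tiny("drug", c("case_id,drug_name", "A,cisplatin")),
               "involvement.*start_date|involvement")
})

test_that("undecodable bytes raise an encoding error naming the line", {
  f <- tempfile(fileext = ".csv")
  con <- file(f, "wb")
  writeBin(c(charToRaw("case_id,sex,age,reporting_year\nA,m"),
             as.raw(0x80), charToRaw("x,60s,2015\n")), con)
  close(con)
  err <- expect_error(read_jader_table(f, "demo"), "line 2")
  expect_s3_class(err, "pvsignal_encoding_error")
})

test_that("an empty case identifier is rejected", {
  expect_error(read_tiny("hist", c("case_id,condition", ",Lung cancer")),
               "case_id")
})

test_that("merge attaches children by case id and counts orphans", {
  demo <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                              "A,male,60s,2015", "B,female,50s,2016"))
  drug <- read_tiny("drug", c("case_id,drug_name,involvement,start_date",
                              "A,cisplatin,suspected,2015-01-01",
                              "A,etoposide,suspected,2015-01-02",
                              "C,cisplatin,suspected,2015-01-03"))
  reac <- read_tiny("reac", c("case_id,term,onset_date,outcome"))
  hist <- read_tiny("hist", c("case_id,condition"))
  expect_message(rs <- merge_tables(demo, drug, reac, hist),
                 "1 orphan")
  expect_equal(n_reports(rs), 2L)
  expect_equal(sum(rs$drugs$case_id == "A"), 2L)
  expect_equal(sum(rs$drugs$case_id == "B"), 0L)
  expect_equal(attr(rs, "n_orphans"), 1L)
  # drug order within the report is file order
  expect_equal(rs$drugs$drug_name[rs$drugs$case_id == "A"],
               c("cisplatin", "etoposide"))
})

test_that("duplicate demographics rows resolve to the highest revision, else the last row", {
  demo <- read_tiny("demo", c("case_id,sex,age,reporting_year,revision",
                              "A,male,60s,2015,2",
                              "A,female,50s,2016,1",
                              "B,male,30s,2015,1",
                              "B,female,40s,2017,2"))
  empty_drug <- read_tiny("drug", c("case_id,drug_name,involvement,start_date"))
  empty_reac <- read_tiny("reac", c("case_id,term,onset_date,outcome"))
  empty_hist <- read_tiny("hist", c("case_id,condition"))
  rs <- merge_tables(demo, empty_drug, empty_reac, empty_hist, quiet = TRUE)
  expect_equal(attr(rs, "n_duplicates"), 2L)
  expect_equal(rs$demo$sex[rs$demo$case_id == "A"], "male")    # revision 2
  expect_equal(rs$demo$age_band[rs$demo$case_id == "B"], "40s")

  # without a revision column the last occurrence wins
  demo2 <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                               "A,male,60s,2015", "A,female,50s,2016"))
  rs2 <- merge_tables(demo2, empty_drug, empty_reac, empty_hist, quiet = TRUE)
  expect_equal(rs2$demo$sex, "female")
})

test_that("date and age parsing follow the declared conventions", {
  demo <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                              "A,male,63,2015",        # numeric age binned
                              "B,female,60歳代,2016",   # JADER band
                              "C,female,elderly,2017")) # non-band -> unknown
  drug <- read_tiny("drug", c("case_id,drug_name,involvement,start_date",
                              "A,x,suspected,20150301",
                              "B,x,suspected,2016-05",   # partial -> missing
                              "C,x,suspected,"))
  rs <- merge_tables(demo, drug,
                     read_tiny("reac", "case_id,term,onset_date,outcome"),
                     read_tiny("hist", "case_id,condition"), quiet = TRUE)
  expect_equal(rs$demo$age_band, c("60s", "60s", "unknown"))
  expect_equal(rs$drugs$start_date,
               as.Date(c("2015-03-01", NA, NA)))
  expect_equal(rs$demo$reporting_year, c(2015L, 2016L, 2017L))
})

test_that("filter_valid keeps exactly the records with known sex and age", {
  demo <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                              "A,male,60s,2015",
                              "B,,50s,2016",
                              "C,female,,2017",
                              "D,female,70s,2018"))
  rs <- merge_tables(demo,
                     read_tiny("drug", "case_id,drug_name,involvement,start_date"),
                     read_tiny("reac", "case_id,term,onset_date,outcome"),
                     read_tiny("hist", "case_id,condition"), quiet = TRUE)
  rv <- filter_valid(rs)
  expect_equal(rv$demo$case_id, c("A", "D"))
  expect_equal(attr(rv, "n_excluded"), 2L)
  expect_equal(n_reports(rv) + attr(rv, "n_excluded"), n_reports(rs))
})

test_that("exclusion counts balance for generated data with injected missingness", {
  cfg <- observed_config(seed = 3L, n = 800L,
                         missingness = list(sex = 0.05, age = 0.05,
                                            start_date = 0, onset_date = 0))
  gen <- generate_reports(cfg)
  rs <- merge_tables(gen$tables$demo, gen$tables$drug, gen$tables$reac,
                     gen$tables$hist, quiet = TRUE)
  rv <- filter_valid(rs)
  miss <- gen$truth$missing
  expect_equal(n_reports(rs), 800L)
  expect_equal(attr(rv, "n_excluded"), sum(miss$sex | miss$age))
  expect_equal(n_reports(rv) + attr(rv, "n_excluded"), 800L)
})

test_that("merging is idempotent on an already de-duplicated report set", {
  gen <- generate_reports(observed_config(seed = 9L, n = 300L))
  rs1 <- merge_tables(gen$tables$demo, gen$tables$drug, gen$tables$reac,
                      gen$tables$hist, quiet = TRUE)
  rs2 <- merge_tables(gen$tables$demo, gen$tables$drug, gen$tables$reac,
                      gen$tables$hist, quiet = TRUE)
  expect_identical(rs1$demo, rs2$demo)
  expect_identical(rs1$drugs, rs2$drugs)
  expect_identical(rs1$events, rs2$events)
  expect_identical(rs1$conditions, rs2$conditions)
})

test_that("write_report_set emits one row per report entity", {
  rs <- tiny_report_set()
  f <- tempfile(fileext = ".tsv")
  write_report_set(rs, f)
  long <- utils::read.delim(f, colClasses = "character")
  expect_equal(sum(long$entity == "report"), n_reports(rs))
  expect_equal(sum(long$entity == "drug"), nrow(rs$drugs))
  expect_equal(sum(long$entity == "condition"), nrow(rs$conditions))
})
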