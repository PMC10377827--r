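test_that("panel validation enforces disjoint, non-degenerate roles", {
  p <- tiny_panel()
  expect_s3_class(p, "panel_definition")
  expect_length(panel_assays(p), 7)

  expect_error(panel_definition("A", character(0), "S", c("A", "A")),
               "distinct")
  expect_error(panel_definition(c("SNORD61", "A", "B"), "SNORD61", "S", c("A", "B")),
               "duplicate")
  expect_error(panel_definition(character(0), "SNORD61", "S", c("A", "B")),
               "at least one target")
  expect_error(panel_definition(c("A", "B"), "C", "S", c("A", "Z")),
               "hemolysis_pair")
})

test_that("the packaged serum panel has the expected composition", {
  p <- default_serum_panel()
  expect_length(p$targets, 372)
  expect_length(p$endogenous_controls, 6)
  expect_length(panel_assays(p), 379)
  expect_true(all(p$hemolysis_pair %in% p$targets))
  # deterministic and order-preserving
  expect_identical(p$targets, default_serum_panel()$targets)
})

test_that("load_panel reads YAML and JSON and rejects broken configs", {
  cfg <- list(name = "t", targets = c("A", "B"), endogenous_controls = "C",
              spike_in = "S", hemolysis_pair = c("A", "B"))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_identical(suppressMessages(load_panel(yml))$targets,
                   suppressMessages(load_panel(jsn))$targets)

  cfg$hemolysis_pair <- NULL
  yaml::write_yaml(cfg, yml)
  expect_error(suppressMessages(load_panel(yml)), "missing fields")
})

test_that("long and wide Ct layouts parse to the identical matrix", {
  pan <- tiny_panel()
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,assay,ct",
               "s1,control,hsa-miR-195-5p,24.5",
               "s1,control,hsa-miR-1281,Undetermined",
               "s1,control,hsa-miR-23a-3p,26",
               "s2,IFG,hsa-miR-195-5p,23.1",
               "s2,IFG,hsa-miR-1281,30",
               "s2,IFG,hsa-miR-23a-3p,25.8"), long)
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("assay,s1,s2",
               "hsa-miR-195-5p,24.5,23.1",
               "hsa-miR-1281,,30",
               "hsa-miR-23a-3p,26,25.8"), wide)

  a <- read_ct_table(long, "long", pan)
  b <- read_ct_table(wide, "wide", pan, groups = c(s1 = "control", s2 = "IFG"))
  expect_equal(unclass(a)[rownames(b), ], unclass(b)[, ],
               ignore_attr = TRUE)
  expect_identical(sum(is.na(a)), 1L)
  expect_identical(unname(ct_groups(a)), c("control", "IFG"))
})

test_that("Ct parsing rejects duplicates, bad numbers and out-of-range values", {
  pan <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,assay,ct",
               "s1,control,hsa-miR-195-5p,24",
               "s1,control,hsa-miR-195-5p,25"), f)
  expect_error(read_ct_table(f, "long", pan), "hsa-miR-195-5p, s1")

  writeLines(c("sample,group,assay,ct", "s1,control,hsa-miR-195-5p,abc"), f)
  expect_error(read_ct_table(f, "long", pan), "non-numeric")

  writeLines(c("sample,group,assay,ct", "s1,control,hsa-miR-195-5p,46.2"), f)
  expect_error(read_ct_table(f, "long", pan), "\\[0, 45\\]")

  writeLines(c("sample,group,assay,ct",
               "s1,control,hsa-miR-195-5p,24",
               "s1,control,hsa-miR-999,24"), f)
  expect_error(read_ct_table(f, "long", pan, strict = TRUE), "not in panel")
  expect_warning(kept <- read_ct_table(f, "long", pan, strict = FALSE), "dropping")
  expect_identical(rownames(kept), "hsa-miR-195-5p")
})

test_that("Ct matrix round-trips through the long CSV writer", {
  pan <- tiny_panel()
  ct <- tiny_ct(list(s1 = c("hsa-miR-23a-3p" = 26, "hsa-miR-451a" = 24,
                            "hsa-miR-195-5p" = NA),
                     s2 = c("hsa-miR-23a-3p" = 25.5, "hsa-miR-451a" = 23.9,
                            "hsa-miR-195-5p" = 31.25)),
                c("control", "IFG"), panel = pan)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, f)
  back <- read_ct_table(f, "long", pan)
  expect_equal(unclass(back)[rownames(ct), colnames(ct)], unclass(ct)[, ],
               ignore_attr = TRUE)
})

test_that("comparison fixtures parse printed values including unicode minus", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mature_id\tfold_regulation",
               "hsa-miR-4301\t124.8",
               "hsa-miR-328-3p\t−52.22"), f)
  fx <- read_comparison_fixture(f)
  expect_equal(fx$fold_regulation, c(124.8, -52.22))

  writeLines(c("mature_id\tfold_regulation", "x\t0.5"), f)
  expect_error(read_comparison_fixture(f), "\\|FR\\| < 1")

  writeLines(c("mature_id\tfold_regulation", "a\t2", "a\t3"), f)
  expect_error(read_comparison_fixture(f), "duplicate")
})

test_that("comparison tables are written sorted and round-trip at 2 decimals", {
  rec <- rec_df(c("c", "b", "a"), c(3.004, -2.5, 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_table(rec, f)
  back <- read_comparison_fixture(f)
  expect_identical(back$mirna, c("a", "c", "b"))
  expect_equal(back$fold_regulation, c(11, 3, -2.5))

  # ties broken by ID ascending
  write_comparison_table(rec_df(c("b", "a"), c(2, 2)), f)
  expect_identical(read_comparison_fixture(f)$mirna, c("a", "b"))
})

test_that("typographic quirks in the shipped fixtures are normalized on read", {
  fx <- packaged_fixtures()
  expect_true("hsa-miR-154-5p" %in% fx$t2d_vs_control$mirna)
  expect_true("hsa-miR-433-3p" %in% fx$t2d_vs_control$mirna)
  expect_true(all(abs(fx$ifg_vs_control$fold_regulation) >= 1))
})
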