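# Data input, configuration, report output, fixtures, and the CLI.

test_that("long and wide layouts produce identical datasets", {
  wide <- tiny_dataset()
  conf <- tiny_config()
  long <- tidyr::pivot_longer(wide, -subject, names_to = "var", values_to = "response") %>%
    tidyr::separate(var, c("item", "occasion"), sep = "@") %>%
    dplyr::rename(subject_id = subject) %>%
    dplyr::mutate(occasion = as.integer(occasion))
  from_long <- read_ordinal_data(long, conf, layout = "long")
  from_wide <- read_ordinal_data(wide, conf, layout = "wide")
  cols <- c("item_1@1", "item_1@2", "item_2@1", "item_2@2")
  expect_equal(as.data.frame(from_long[order(from_long$subject), cols]),
               as.data.frame(from_wide[order(from_wide$subject), cols]))
})

test_that("validation errors carry row information", {
  wide <- tiny_dataset()
  wide[["item_1@1"]][5] <- 7L
  expect_error(read_ordinal_data(wide, tiny_config()), "1..4.*row 5")
  long_dup <- tibble::tibble(subject_id = c(1, 1), occasion = 1, item = "item_1",
                             response = c(2, 3))
  expect_error(read_ordinal_data(long_dup, tiny_config(), layout = "long"), "duplicate")
  long_bad <- tibble::tibble(subject_id = 1, occasion = 1, item = "mystery", response = 1)
  expect_error(read_ordinal_data(long_bad, tiny_config(), layout = "long"), "unknown item")
})

test_that("reverse coding is an involution", {
  wide <- tiny_dataset()
  items <- tiny_config()$items
  items$reverse <- c(TRUE, FALSE)
  conf_rev <- scale_config(items)
  once <- read_ordinal_data(wide, conf_rev)
  expect_equal(once[["item_1@1"]], 5L - wide[["item_1@1"]])
  expect_equal(once[["item_2@1"]], wide[["item_2@1"]])
  twice <- read_ordinal_data(once, conf_rev)
  expect_equal(twice[["item_1@1"]], wide[["item_1@1"]])
})

test_that("listwise deletion drops and logs incomplete subjects", {
  wide <- tiny_dataset()
  wide[["item_2@2"]][3] <- NA
  expect_message(s1 <- run_stage1(wide, tiny_config(), acov = FALSE),
                 "listwise deletion: 1")
  expect_equal(s1$n, nrow(wide) - 1L)
})

test_that("reports are deterministic and JSON round-trips", {
  cfg <- sim_config(n_subjects = 250, n_items = 3, m = 5,
                    thresholds = seq(-1, 1, length.out = 4), seed = 52)
  s1 <- run_stage1(simulate_ordinal(cfg), sim_scale_config(cfg), acov = FALSE)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(s1, f1); write_report(s1, f2)
  expect_identical(readLines(f1), readLines(f2))
  payload <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_equal(payload$kind, "stage1")
  expect_equal(nrow(payload$stage1), 3)
  ftxt <- tempfile(fileext = ".txt")
  write_report(s1, ftxt, format = "text")
  expect_true(any(grepl("stage1", readLines(ftxt))))
})

test_that("packaged reference tables are consistent", {
  fr <- sf36_item_frequencies()
  # worked example row: MH item 24 baseline counts
  expect_equal(unname(sf36_margins("24", 1)), c(14, 30, 55, 182, 91, 64))
  # row sums are the study sample size, up to documented misprints
  sums <- apply(fr[, paste0("c", 1:6)], 1, sum, na.rm = TRUE)
  bad <- c(which(fr$item == "5" & fr$occasion == 2),
           which(fr$item == "31" & fr$occasion == 2))
  expect_true(all(sums[-bad] >= 436 & sums[-bad] <= 437))
  st1 <- sf36_stage1_estimates()
  expect_equal(st1$sd_pre[st1$item == "13"], 1.00)
  expect_equal(st1$sd_post[st1$item == "13"], 1.00)
  # df column: 3 for 6 categories, 2 for 5, NA for 3 and 2
  expect_true(all(st1$inv_df[st1$m == 6] == 3, na.rm = TRUE))
  expect_true(all(st1$inv_df[st1$m == 5] == 2, na.rm = TRUE))
  expect_true(all(is.na(st1$inv_df[st1$m <= 3])))
  conf <- sf36_scale_config()
  expect_equal(nrow(conf$items), 36L)
  expect_equal(sum(conf$items$scale == "PF"), 10L)
})

test_that("the CLI simulates, analyzes and reports", {
  out_csv <- tempfile(fileext = ".csv")
  code <- ordshift_cli(c("simulate", "--n", "60", "--items", "2", "--m", "4",
                         "--seed", "7", "--out", out_csv, "--log-level", "quiet"))
  expect_equal(code, 0L)
  dat <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_equal(nrow(dat), 60L)
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(items = data.frame(item = c("item_1", "item_2"),
                                               scale = "toy", m = 4)),
                       cfg_json, auto_unbox = TRUE)
  rep_json <- tempfile(fileext = ".json")
  code <- ordshift_cli(c("stage1", "--data", out_csv, "--config", cfg_json,
                         "--out", rep_json, "--log-level", "quiet"))
  expect_equal(code, 0L)
  expect_true(file.exists(rep_json))
  rep_txt <- tempfile(fileext = ".txt")
  code <- ordshift_cli(c("report", "--in", rep_json, "--out", rep_txt))
  expect_equal(code, 0L)
  # usage errors exit with 2
  expect_equal(suppressMessages(ordshift_cli(character())), 2L)
  expect_equal(suppressMessages(ordshift_cli(c("stage1", "oops"))), 2L)
  expect_equal(suppressMessages(ordshift_cli(c("nonsense", "--x", "1"))), 2L)
})

test_that("plot methods return ggplot objects", {
  cfg <- sim_config(n_subjects = 300, n_items = 3, m = 5,
                    thresholds = seq(-1, 1, length.out = 4), seed = 53)
  dat <- simulate_ordinal(cfg)
  s1 <- run_stage1(dat, sim_scale_config(cfg), acov = FALSE)
  expect_s3_class(ggplot2::autoplot(s1), "ggplot")
  res <- suppressWarnings(detect_response_shift(dat, sim_scale_config(cfg)))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
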