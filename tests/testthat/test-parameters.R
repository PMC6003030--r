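# Built-in base-case inputs and the configuration machinery.

test_that("built-in fixture reproduces every published input cell", {
  tab <- parameter_table(tpl_parameters())
  expected <- tibble::tribble(
    ~name,                  ~point, ~low,  ~high, ~family,
    "incidence",             0.097, 0.05,  0.15,  "fixed",
    "S_ref.sensitivity",     0.78,  0.68,  0.87,  "beta",
    "S_ref.specificity",     0.71,  0.67,  0.74,  "beta",
    "S2.sensitivity",        0.75,  0.66,  0.83,  "beta",
    "S2.specificity",        0.76,  0.73,  0.79,  "beta",
    "S3.sensitivity",        0.59,  0.36,  0.95,  "beta",
    "S3.specificity",        0.94,  0.91,  0.97,  "beta",
    "S4.sensitivity",        0.83,  0.53,  1.00,  "beta",
    "S4.specificity",        0.94,  0.89,  0.99,  "beta",
    "S5.sensitivity",        0.74,  0.63,  0.85,  "beta",
    "S5.specificity",        0.86,  0.79,  0.93,  "beta",
    "S6.sensitivity",        0.60,  0.53,  0.67,  "beta",
    "S6.specificity",        0.90,  0.89,  0.92,  "beta",
    "S7.sensitivity",        0.89,  0.83,  0.95,  "beta",
    "S7.specificity",        0.70,  0.67,  0.73,  "beta",
    "24-27.p_death",         0.392, 0.35,  0.44,  "beta",
    "28-31.p_death",         0.078, 0.05,  0.10,  "beta",
    "32-34.p_death",         0.033, 0.009, 0.057, "beta",
    "24-27.p_morbidity",     0.303, 0.25,  0.36,  "beta",
    "28-31.p_morbidity",     0.085, 0.059, 0.11,  "beta",
    "32-34.p_morbidity",     0.016, 0,     0.034, "beta",
    "pooled_24-34.p_death",  0.109, 0.09,  0.13,  "fixed",
    "pooled_24-34.p_morbidity", 0.07, 0.054, 0.086, "fixed",
    "24-27.p_subsequent_hosp", 0.13, 0.13, 0.13,  "fixed",
    "28-31.p_subsequent_hosp", 0.17, 0.17, 0.17,  "fixed",
    "32-34.p_subsequent_hosp", 0.27, 0.27, 0.27,  "fixed",
    "24-27.p_home_followup", 0.94,  0.94,  0.94,  "fixed",
    "28-31.p_home_followup", 0.938, 0.938, 0.938, "fixed",
    "32-34.p_home_followup", 0.916, 0.916, 0.916, "fixed",
    "24-27.cost.weekly_home_followup", 42, 42, 42, "fixed",
    "24-27.cost.prenatal_hosp_tpl",    1445, 532, 2736,  "gamma",
    "24-27.cost.preterm_labor",        2877, 1327, 11570, "lognormal",
    "24-27.cost.preterm_labor_hosp",   2890, 1332, 11594, "lognormal",
    "24-27.cost.perinatal_death",      1867, 323, 80068,  "lognormal",
    "24-27.cost.neonatal_hosp_no_morbidity",   27295, 1380, 78887, "lognormal",
    "24-27.cost.neonatal_hosp_with_morbidity", 58775, 2406, 79591, "gamma",
    "28-31.cost.prenatal_hosp_tpl",    1762, 532, 5370,   "gamma",
    "28-31.cost.preterm_labor",        3606, 1318, 11525, "lognormal",
    "28-31.cost.preterm_labor_hosp",   3639, 1328, 11626, "lognormal",
    "28-31.cost.perinatal_death",      1235, 323, 18976,  "lognormal",
    "28-31.cost.neonatal_hosp_no_morbidity",   19748, 1380, 79394, "lognormal",
    "28-31.cost.neonatal_hosp_with_morbidity", 40419, 2150, 79690, "gamma",
    "32-34.cost.prenatal_hosp_tpl",    2113, 532, 11625,  "gamma",
    "32-34.cost.preterm_labor",        4482, 1334, 11625, "lognormal",
    "32-34.cost.preterm_labor_hosp",   4517, 1343, 11821, "lognormal",
    "32-34.cost.perinatal_death",      1606, 323, 57387,  "lognormal",
    "32-34.cost.neonatal_hosp_no_morbidity",   10907, 1380, 61756, "lognormal",
    "32-34.cost.neonatal_hosp_with_morbidity", 20331, 1380, 36321, "gamma")
  for (i in seq_len(nrow(expected))) {
    row <- tab[tab$name == expected$name[i], ]
    expect_equal(nrow(row), 1, info = expected$name[i])
    expect_equal(row$point, expected$point[i], info = expected$name[i])
    expect_equal(row$low, expected$low[i], info = expected$name[i])
    expect_equal(row$high, expected$high[i], info = expected$name[i])
    expect_equal(row$family, expected$family[i], info = expected$name[i])
  }
})

test_that("fixture passes validation and carries entry weeks inside strata", {
  p <- tpl_parameters()
  expect_equal(nrow(validate_parameters(p)), 0)
  expect_equal(vapply(p$strata, function(s) s$entry_week, 0),
               c(`24-27` = 25, `28-31` = 29, `32-34` = 33))
  expect_equal(sum(p$ga_weights), 1)
})

test_that("override semantics: partial, empty, unknown and invalid configs", {
  base <- tpl_parameters()
  p <- tpl_parameters(list(incidence = 0.05))
  expect_equal(p$incidence$point, 0.05)
  p$incidence <- base$incidence
  expect_equal(p, base)

  expect_equal(load_parameters(NULL), base)
  expect_equal(load_parameters(list()), base)

  expect_error(tpl_parameters(list(no_such_key = 1)),
               class = "tpl_config_error")
  expect_error(
    tpl_parameters(list(strategies = list(S7 = list(
      sensitivity = uparam(1.2, 1.2, 1.2, "fixed"))))),
    class = "tpl_validation_error")
})

test_that("validation reports each violated rule with its field", {
  p <- tpl_parameters()
  p$ga_weights <- c(0.5, 0.5, 0.5)
  v <- validate_parameters(p)
  expect_equal(nrow(v), 1)
  expect_match(v$field, "ga_weights")

  p2 <- tpl_parameters()
  p2$strata$`24-27`$p_morbidity$point <- 0.7
  v2 <- validate_parameters(p2)
  expect_true(any(grepl("death_morbidity_sum", v2$rule)))
  expect_true(any(grepl("morbidity > 1|> 1", v2$message)))
})

test_that("parameters round-trip through the YAML configuration format", {
  p <- tpl_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- load_parameters(path)
  expect_equal(p2, p, tolerance = 1e-9)

  # a modified set round-trips too
  pm <- suppressWarnings(tpl_parameters(list(
    incidence = 0.12,
    ga_weights = c(`24-27` = 0.2, `28-31` = 0.3, `32-34` = 0.5))))
  write_parameters(pm, path)
  expect_equal(load_parameters(path), pm, tolerance = 1e-9)
})

test_that("JSON configurations load like YAML ones", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(incidence = list(point = 0.05)), path,
                       auto_unbox = TRUE, digits = NA)
  p <- load_parameters(path)
  expect_equal(p$incidence$point, 0.05)
})

test_that("parameter table is export-ready", {
  tab <- parameter_table(tpl_parameters())
  expect_named(tab, c("name", "point", "low", "high", "family", "source"))
  expect_true(all(tab$low <= tab$point & tab$point <= tab$high))
  expect_setequal(unique(tab$family), c("fixed", "beta", "gamma", "lognormal"))
})
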