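# Single-cell hand fixture: one chapter, one stratum.
one_cell_inputs <- function(share = 1, attendances = 1000, incident = 100,
                            prevalent = 400, persons = 10000,
                            pa_share = 0) {
  list(
    attendances = tibble::tibble(sex = "male", age_band = "45_54",
                                 consultations = attendances),
    mix = dplyr::bind_rows(
      tibble::tibble(chapter = "respiratory", sex = "male",
                     age_band = "45_54", proportion = share),
      if (pa_share > 0) tibble::tibble(chapter = "prevent_admin",
                                       sex = "male", age_band = "45_54",
                                       proportion = pa_share)
    ),
    burden = tibble::tibble(chapter = "respiratory", sex = "male",
                            age_band = "45_54", incident_cases = incident,
                            prevalent_cases = prevalent),
    population = tibble::tibble(sex = "male", age_band = "45_54",
                                persons = persons),
    lengths = tibble::tibble(sex = "male", age_band = "45_54",
                             mean_minutes = 15)
  )
}

test_that("service-profile fit inverts shares over incident plus prevalent cases", {
  inp <- one_cell_inputs(share = 1, attendances = 1000, incident = 100,
                         prevalent = 400)
  prof <- fit_service_profile(inp$attendances, inp$mix, inp$burden,
                              inp$population, inp$lengths)
  expect_equal(prof$per_case$per_case, 2) # 1000 x 1 / 500
  # zero share gives zero per-case rate regardless of cases
  inp0 <- one_cell_inputs(share = 0)
  prof0 <- fit_service_profile(inp0$attendances, inp0$mix, inp0$burden,
                               inp0$population, inp0$lengths)
  expect_equal(prof0$per_case$per_case, 0)
  # positive share with zero cases names the offending cell
  inp_bad <- one_cell_inputs(incident = 0, prevalent = 0)
  expect_error(
    fit_service_profile(inp_bad$attendances, inp_bad$mix, inp_bad$burden,
                        inp_bad$population, inp_bad$lengths),
    "respiratory.*male 45_54", class = "gp_fit_error")
})

test_that("generate-then-fit recovers the true service profile exactly", {
  cfg <- fixture_config(seed = 3, preset = "toy")
  fx <- gen_need_fixture(cfg)
  prof <- fit_service_profile(fx$attendances, fx$mix, fx$burden,
                              fx$population[fx$population$year ==
                                              fx$base_year, ],
                              fx$lengths)
  got <- dplyr::inner_join(
    prof$per_case, fx$profile_true$per_case,
    by = c("chapter", "sex", "age_band"), suffix = c("_fit", "_true"))
  expect_equal(nrow(got), nrow(fx$profile_true$per_case))
  expect_equal(got$per_case_fit, got$per_case_true, tolerance = 1e-9)
  pa <- dplyr::inner_join(prof$prevent_admin, fx$profile_true$prevent_admin,
                          by = c("sex", "age_band"),
                          suffix = c("_fit", "_true"))
  expect_equal(pa$per_capita_fit, pa$per_capita_true, tolerance = 1e-9)
})

test_that("burden projection scales with population and compounds growth", {
  cfg <- fixture_config(seed = 5, preset = "toy", pop_growth = 0)
  fx <- gen_need_fixture(cfg)
  base <- fx$base_year
  # static population, growth 1 -> constant cases
  b0 <- project_burden(fx$burden, fx$population, year = base + 7,
                       base_year = base, growth = 1)
  expect_equal(b0$cases,
               fx$burden$incident_cases + fx$burden$prevalent_cases,
               tolerance = 1e-12)
  # static population, 2%/year over 10 years -> x 1.02^10
  b2 <- project_burden(fx$burden, fx$population, year = base + 10,
                       base_year = base, growth = 1.02)
  expect_equal(b2$cases, b0$cases * 1.02^10, tolerance = 1e-12)
  expect_equal(1.02^10, 1.21899, tolerance = 1e-5)
  # doubling one population cell doubles that cell's cases
  pop2 <- dplyr::mutate(
    fx$population,
    persons = ifelse(sex == "male" & age_band == "under_35" &
                       year == base + 1, persons * 2, persons))
  b3 <- project_burden(fx$burden, pop2, year = base + 1, base_year = base)
  b1 <- project_burden(fx$burden, fx$population, year = base + 1,
                       base_year = base)
  ratio <- b3$cases / b1$cases
  cell <- b1$sex == "male" & b1$age_band == "under_35"
  expect_equal(ratio[cell], rep(2, sum(cell)))
  expect_equal(ratio[!cell], rep(1, sum(!cell)))
  # missing population cell is a schema error
  expect_error(project_burden(fx$burden, fx$population, year = base + 99,
                              base_year = base),
               class = "gp_schema_error")
})

test_that("base-year projection reproduces observed attendances exactly", {
  cfg <- fixture_config(seed = 7, preset = "toy")
  fx <- gen_need_fixture(cfg)
  pop0 <- fx$population[fx$population$year == fx$base_year, ]
  prof <- fit_service_profile(fx$attendances, fx$mix, fx$burden, pop0,
                              fx$lengths)
  cons <- project_consultations(prof, fx$burden, pop0, utilisation = 1,
                                k = 0)
  cmp <- dplyr::inner_join(cons, fx$attendances, by = c("sex", "age_band"))
  expect_equal(cmp$consultations.x, cmp$consultations.y, tolerance = 1e-9)
})

test_that("one year of utilisation growth multiplies condition volume by 1.0112", {
  inp <- one_cell_inputs(share = 1, attendances = 1000, incident = 100,
                         prevalent = 400)
  prof <- fit_service_profile(inp$attendances, inp$mix, inp$burden,
                              inp$population, inp$lengths)
  base_burden <- dplyr::mutate(inp$burden,
                               cases = incident_cases + prevalent_cases)
  c0 <- project_consultations(prof, base_burden, inp$population,
                              utilisation = 1.0112, k = 0)
  c1 <- project_consultations(prof, base_burden, inp$population,
                              utilisation = 1.0112, k = 1)
  expect_equal(c0$consultations, 1000)
  expect_equal(c1$consultations, 1000 * 1.0112, tolerance = 1e-12)
})

test_that("with zero burden only preventive/administrative volume remains", {
  inp <- one_cell_inputs(share = 0, pa_share = 0.2, attendances = 1000,
                         persons = 10000)
  prof <- fit_service_profile(inp$attendances, inp$mix, inp$burden,
                              inp$population, inp$lengths)
  zero_burden <- dplyr::mutate(inp$burden, cases = 0)
  cons <- project_consultations(prof, zero_burden, inp$population)
  expect_equal(cons$consultations, 1000 * 0.2) # pa share of attendances
})

test_that("FTE conversion follows the minutes chain", {
  prof <- hours_profile() # 1760 h/year
  len60 <- tibble::tibble(sex = "male", age_band = "45_54",
                          mean_minutes = 60)
  c1760 <- tibble::tibble(sex = "male", age_band = "45_54",
                          consultations = 1760)
  expect_equal(consultations_to_fte(c1760, len60, prof), 1)
  len15 <- dplyr::mutate(len60, mean_minutes = 15)
  c105600 <- dplyr::mutate(c1760, consultations = 105600)
  expect_equal(consultations_to_fte(c105600, len15, prof), 15)
  expect_error(
    consultations_to_fte(c1760, dplyr::mutate(len60, mean_minutes = 0),
                         prof),
    class = "gp_config_error")
})

test_that("7.6M consultations at the implied mean length give 1140 FTE", {
  # plausibility cross-check: mean length consistent with the base-year
  # totals is 1140 x 1760 x 60 / 7607928 ~ 15.823 minutes
  implied <- 1140 * 1760 * 60 / 7607928
  expect_equal(implied, 15.823, tolerance = 1e-4)
  cons <- tibble::tibble(sex = "male", age_band = "45_54",
                         consultations = 7607928)
  len <- tibble::tibble(sex = "male", age_band = "45_54",
                        mean_minutes = implied)
  expect_equal(consultations_to_fte(cons, len, hours_profile()), 1140,
               tolerance = 1e-9)
})

test_that("required FTE scales linearly with consultation length", {
  cfg <- fixture_config(seed = 13, preset = "toy")
  fx <- gen_need_fixture(cfg)
  pop0 <- fx$population[fx$population$year == fx$base_year, ]
  prof <- fit_service_profile(fx$attendances, fx$mix, fx$burden, pop0,
                              fx$lengths)
  cons <- project_consultations(prof, fx$burden, pop0)
  f1 <- consultations_to_fte(cons, fx$lengths, hours_profile())
  f2 <- consultations_to_fte(
    cons, dplyr::mutate(fx$lengths, mean_minutes = mean_minutes * 1.7),
    hours_profile())
  expect_equal(f2, 1.7 * f1, tolerance = 1e-12)
})

test_that("burden categories recode and aggregate through the crosswalk", {
  burden <- tibble::tibble(
    chapter = c("bod_group_1", "bod_group_2", "bod_group_3"),
    sex = "male", age_band = "45_54",
    incident_cases = c(10, 20, 30), prevalent_cases = c(1, 2, 3))
  mapping <- tibble::tibble(
    source_category = paste0("bod_group_", 1:3),
    icpc2_chapter = c("respiratory", "respiratory", "circulatory"))
  out <- map_burden_categories(burden, mapping)
  expect_equal(out$incident_cases[out$chapter == "respiratory"], 30)
  expect_equal(out$prevalent_cases[out$chapter == "circulatory"], 3)
  expect_error(
    map_burden_categories(
      dplyr::mutate(burden, chapter = "unmapped"), mapping),
    class = "gp_schema_error")
})
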