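# Seeded synthetic fixtures with known ground truth for every input table.
#
# The supply fixture draws nothing from real workforce data: a fixed true
# transition table and multiplier set generate the observed target series
# (optionally perturbed by multiplicative lognormal noise, headcounts being
# positive), and the shipped priors are informative distributions centred on
# the truth -- emulating expert-revised priors rather than raw survey rates.
# The need fixture is built backwards from a true service profile so that
# fitting recovers it exactly and attendance totals reconstruct.

#' Configure a synthetic fixture
#'
#' @param seed Integer; fixes every generated artefact bit-for-bit.
#' @param preset `"toy"` (2 sexes x 2 age bands x urban only; fast oracle
#'   tests) or `"paper_like"` (5 bands x 2 sexes x 2 locations, entry counts
#'   42 graduates and 47 in-migrants, supply base year 2003 with 8 target
#'   years, need base year 2003 with a 10-year horizon).
#' @param noise Multiplicative lognormal noise sd (log scale) on the
#'   observed supply targets; default 0 (noise-free).
#' @param horizon Supply projection years covered by the target series.
#' @param beta_ess Effective sample size `alpha + beta` of the beta priors
#'   centred on the true probabilities.
#' @param mult_halfwidth Half-width of the uniform multiplier priors around
#'   the true multipliers (clipped to the -0.10..0.10 bound).
#' @param pop_growth Annual population growth rate in the need fixture.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, preset = c("toy", "paper_like"),
                           noise = 0, horizon = 8L, beta_ess = 2000,
                           mult_halfwidth = 0.02, pop_growth = 0.01) {
  preset <- match.arg(preset)
  if (noise < 0) abort("`noise` must be >= 0.", class = "gp_config_error")
  dims <- if (preset == "toy") {
    list(sexes = gp_sexes, bands = c("under_35", "35_44"),
         locations = "urban")
  } else {
    list(sexes = gp_sexes, bands = age_bands()$label,
         locations = gp_locations)
  }
  chapters <- if (preset == "toy") {
    c("respiratory", "circulatory", "musculoskeletal")
  } else {
    c("general_unspecified", "blood_immune", "digestive", "eye", "ear",
      "circulatory", "musculoskeletal", "neurological", "psychological",
      "respiratory", "skin", "endocrine_metabolic", "urological",
      "pregnancy_family_planning", "female_genital", "male_genital",
      "infections")
  }
  structure(
    list(seed = as.integer(seed), preset = preset, dims = dims,
         noise = noise, horizon = as.integer(horizon),
         beta_ess = beta_ess, mult_halfwidth = mult_halfwidth,
         supply_base_year = 2003L, need_base_year = 2003L,
         need_horizon = 10L, chapters = chapters,
         pop_growth = pop_growth),
    class = "fixture_config"
  )
}

# deterministic (seed-free) true parameter values: smooth functions of the
# stratum indices so every stratum differs but nothing is sampled
true_transition_table <- function(cfg) {
  d <- cfg$dims
  strata <- tidyr::expand_grid(sex = d$sexes, age_band = d$bands)
  strata$si <- match(strata$sex, d$sexes)
  strata$bi <- match(strata$age_band, d$bands)
  nb <- length(d$bands)
  rows <- purrr::pmap_dfr(strata, function(sex, age_band, si, bi) {
    ft_pt <- 0.05 + 0.02 * (si - 1) + 0.005 * (bi - 1)
    pt_ft <- 0.04 - 0.01 * (si - 1) + 0.003 * (bi - 1)
    to_tmp <- 0.02 + 0.01 * (si - 1)
    to_prm <- 0.01 + 0.015 * (bi - 1) / max(nb - 1, 1) * 4
    tmp_ret <- 0.5
    tmp_prm <- 0.08
    per_loc <- function(loc) {
      base <- tibble::tibble(
        from_location = loc,
        from_status = c("full_time", "part_time",
                        "full_time", "part_time",
                        "full_time", "part_time",
                        "temporary_exit", "temporary_exit",
                        "temporary_exit"),
        to_location = loc,
        to_status = c("part_time", "full_time",
                      "temporary_exit", "temporary_exit",
                      "permanent_exit", "permanent_exit",
                      "full_time", "part_time",
                      "permanent_exit"),
        probability = c(ft_pt, pt_ft, to_tmp, to_tmp * 1.2,
                        to_prm, to_prm * 1.1,
                        tmp_ret * 0.6, tmp_ret * 0.4, tmp_prm)
      )
      if (length(cfg$dims$locations) > 1L) {
        other <- setdiff(cfg$dims$locations, loc)
        moves <- tidyr::expand_grid(status = gp_active_statuses,
                                    to_location = other)
        base <- dplyr::bind_rows(base, tibble::tibble(
          from_location = loc, from_status = moves$status,
          to_location = moves$to_location, to_status = moves$status,
          probability = ifelse(loc == "urban", 0.01, 0.03)
        ))
      }
      base
    }
    moves <- purrr::map_dfr(cfg$dims$locations, per_loc)
    dplyr::mutate(moves, sex = sex, age_band = age_band, .before = 1)
  })
  transition_table(rows)
}

true_multiplier_set <- function(cfg) {
  tr <- true_transition_table(cfg)
  dplyr::mutate(
    tr[, c("sex", "age_band", "from_location", "from_status",
           "to_location", "to_status")],
    multiplier = ifelse(.data$to_status == "part_time", 0.01,
                        ifelse(.data$to_status == "permanent_exit",
                               0.005, 0))
  )
}

base_stock_table <- function(cfg) {
  d <- cfg$dims
  states <- tidyr::expand_grid(
    sex = d$sexes, age_band = d$bands, location = d$locations,
    status = gp_statuses
  )
  si <- match(states$sex, d$sexes)
  bi <- match(states$age_band, d$bands)
  li <- match(states$location, d$locations)
  n <- dplyr::case_when(
    states$status == "full_time" ~ 260 - 40 * (si - 1) + 10 * bi,
    states$status == "part_time" ~ 120 + 60 * (si - 1) + 5 * bi,
    states$status == "temporary_exit" ~ 12 + 4 * (si - 1),
    TRUE ~ 0
  )
  n <- n * ifelse(li == 1, 1, 0.35)
  if (cfg$preset == "paper_like") {
    # scale active headcount to the baseline stock magnitude (~1789)
    act <- states$status %in% gp_active_statuses
    n[act] <- n[act] * 1789 / sum(n[act])
  }
  tibble::tibble(year = cfg$supply_base_year, sex = states$sex,
                 age_band = states$age_band, location = states$location,
                 status = states$status, headcount = n)
}

fixture_entries <- function(cfg, base_stock) {
  counts <- if (cfg$preset == "paper_like") c(42, 47) else c(24, 12)
  entry_stream(
    tibble::tibble(type = c("graduate", "migrant"), count = counts),
    default_entry_allocation(
      base_stock,
      grad_age_split = if (length(cfg$dims$bands) >= 2) {
        setNames(c(0.7, 0.3), cfg$dims$bands[1:2])
      } else setNames(1, cfg$dims$bands[1])
    )
  )
}

fixture_aging <- function(cfg) {
  dplyr::filter(aging_rule(), .data$age_band %in% cfg$dims$bands)
}

#' Generate a supply-model fixture with known truth
#'
#' Projects the true parameters forward to build an observed target series
#' (active states only), optionally perturbed by multiplicative lognormal
#' noise, and writes informative priors centred on the truth.
#'
#' @param cfg A [fixture_config()].
#' @return List with `base_stock`, `transitions_true`, `multipliers_true`,
#'   `entries`, `aging`, `priors`, `targets`, `truth_projection` and
#'   `base_year`.
#' @export
gen_supply_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  seed_stock <- base_stock_table(cfg)
  tr <- true_transition_table(cfg)
  mu <- true_multiplier_set(cfg)
  entries <- fixture_entries(cfg, seed_stock)
  aging <- fixture_aging(cfg)
  # Burn the cohort in to demographic equilibrium under the base (year-0)
  # probabilities so the target series, like the observed series the model
  # is calibrated to, is well described by per-stratum linear trends.
  burn <- project_supply(seed_stock, tr, entries = entries, aging = aging,
                         horizon = 40)
  base_stock <- dplyr::filter(tibble::as_tibble(burn),
                              .data$year == max(.data$year))
  base_stock$year <- cfg$supply_base_year
  base_stock$headcount[base_stock$status == "permanent_exit"] <- 0
  if (cfg$preset == "paper_like") {
    # anchor the baseline active headcount; entries scale with it so the
    # equilibrium is preserved (dynamics are linear in stock and entries)
    act <- base_stock$status %in% gp_active_statuses
    sc <- 1789 / sum(base_stock$headcount[act])
    base_stock$headcount <- base_stock$headcount * sc
    entries$entries$count <- entries$entries$count * sc
  }
  proj <- project_supply(base_stock, tr, entries = entries, aging = aging,
                         multipliers = mu, horizon = cfg$horizon)
  targets <- dplyr::filter(proj, .data$status %in% gp_active_statuses,
                           .data$year > cfg$supply_base_year)
  targets <- tibble::as_tibble(targets)[
    , c("year", "sex", "age_band", "location", "status", "headcount")]
  if (cfg$noise > 0) {
    fac <- withr::with_seed(cfg$seed,
                            rlnorm(nrow(targets), 0, cfg$noise))
    targets$headcount <- targets$headcount * fac
  }
  priors <- dplyr::mutate(
    dplyr::left_join(tr, mu, by = c("sex", "age_band", "from_location",
                                    "from_status", "to_location",
                                    "to_status")),
    alpha = .data$probability * cfg$beta_ess,
    beta = (1 - .data$probability) * cfg$beta_ess,
    mult_low = pmax(.data$multiplier - cfg$mult_halfwidth, -0.10),
    mult_high = pmin(.data$multiplier + cfg$mult_halfwidth, 0.10),
    probability = NULL, multiplier = NULL
  )
  list(base_stock = base_stock, transitions_true = tr,
       multipliers_true = mu, entries = entries, aging = aging,
       priors = prior_spec(priors), targets = targets,
       truth_projection = proj, base_year = cfg$supply_base_year)
}

#' Generate a need-model fixture with known truth
#'
#' Chooses a true service profile (per-case rates, per-capita preventive/
#' administrative rates, consultation lengths) and a population and burden
#' landscape, then computes attendances and the condition mix forward from
#' the truth so that [fit_service_profile()] recovers every rate exactly and
#' the mix shares sum to 1 per cell.
#'
#' @param cfg A [fixture_config()].
#' @return List with `population`, `burden`, `mix`, `lengths`,
#'   `attendances`, `mapping`, `profile_true` (tibbles of true rates) and
#'   `base_year`.
#' @export
gen_need_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  d <- cfg$dims
  years <- cfg$need_base_year + 0:cfg$need_horizon
  cells <- tidyr::expand_grid(sex = d$sexes, age_band = d$bands)
  cells$si <- match(cells$sex, d$sexes)
  cells$bi <- match(cells$age_band, d$bands)
  base_pop <- 60000 + 15000 * (cells$bi - 1) + 5000 * (cells$si - 1)
  population <- purrr::map_dfr(seq_along(years), function(j) {
    tibble::tibble(year = years[j], sex = cells$sex,
                   age_band = cells$age_band,
                   persons = base_pop * (1 + cfg$pop_growth)^(j - 1))
  })

  ch <- tibble::tibble(chapter = cfg$chapters,
                       ci = seq_along(cfg$chapters))
  grid <- tidyr::expand_grid(ch, cells)
  # true rates: smooth deterministic functions of the indices
  burden <- dplyr::transmute(
    grid, chapter = .data$chapter, sex = .data$sex,
    age_band = .data$age_band,
    incident_cases = round((0.010 + 0.002 * .data$ci + 0.004 * .data$bi) *
                             base_pop[match(paste(.data$sex, .data$age_band),
                                            paste(cells$sex,
                                                  cells$age_band))], 2),
    prevalent_cases = round((0.030 + 0.003 * .data$ci + 0.010 * .data$bi) *
                              base_pop[match(paste(.data$sex,
                                                   .data$age_band),
                                             paste(cells$sex,
                                                   cells$age_band))], 2)
  )
  per_case_true <- dplyr::transmute(
    grid, chapter = .data$chapter, sex = .data$sex,
    age_band = .data$age_band,
    per_case = 0.8 + 0.15 * ((.data$ci + .data$bi + .data$si) %% 5) / 4 +
      0.05 * .data$bi
  )
  pa_true <- dplyr::transmute(
    cells, sex = .data$sex, age_band = .data$age_band,
    per_capita = 1.2 + 0.1 * (.data$bi - 1) + 0.15 * (.data$si - 1)
  )
  lengths <- dplyr::transmute(
    cells, sex = .data$sex, age_band = .data$age_band,
    mean_minutes = 13 + 0.8 * (.data$bi - 1) + 1.5 * (.data$si - 1)
  )

  pop0 <- dplyr::filter(population, .data$year == cfg$need_base_year)
  cases <- dplyr::mutate(burden,
                         cases = .data$incident_cases +
                           .data$prevalent_cases)
  vol <- dplyr::left_join(per_case_true,
                          cases[, c("chapter", "sex", "age_band", "cases")],
                          by = c("chapter", "sex", "age_band"))
  vol$volume <- vol$per_case * vol$cases
  cond_vol <- dplyr::summarise(
    dplyr::group_by(vol, .data$sex, .data$age_band),
    condition = sum(.data$volume), .groups = "drop")
  pa_vol <- dplyr::left_join(pa_true,
                             pop0[, c("sex", "age_band", "persons")],
                             by = c("sex", "age_band"))
  pa_vol$pa <- pa_vol$per_capita * pa_vol$persons
  att <- dplyr::left_join(cond_vol,
                          pa_vol[, c("sex", "age_band", "pa")],
                          by = c("sex", "age_band"))
  attendances <- dplyr::transmute(
    att, year = cfg$need_base_year, sex = .data$sex,
    age_band = .data$age_band,
    consultations = .data$condition + .data$pa)

  att_key <- paste(attendances$sex, attendances$age_band)
  mix_cond <- dplyr::transmute(
    vol, chapter = .data$chapter, sex = .data$sex,
    age_band = .data$age_band,
    proportion = .data$volume /
      attendances$consultations[match(paste(.data$sex, .data$age_band),
                                      att_key)]
  )
  mix_pa <- dplyr::transmute(
    pa_vol, chapter = pa_chapter, sex = .data$sex,
    age_band = .data$age_band,
    proportion = .data$pa /
      attendances$consultations[match(paste(.data$sex, .data$age_band),
                                      att_key)]
  )
  mix <- dplyr::bind_rows(mix_cond, mix_pa)

  mapping <- tibble::tibble(
    source_category = paste0("bod_group_", seq_along(cfg$chapters)),
    icpc2_chapter = cfg$chapters
  )

  list(population = population, burden = burden, mix = mix,
       lengths = lengths, attendances = attendances, mapping = mapping,
       profile_true = list(per_case = per_case_true,
                           prevent_admin = pa_true, lengths = lengths),
       base_year = cfg$need_base_year)
}
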