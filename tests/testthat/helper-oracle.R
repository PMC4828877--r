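# Independent brute-force cohort step: explicit per-(from, to) flow
# enumeration with data-frame loops. Deliberately shares no code with the
# package's indexed engine; used as the oracle for step equivalence.

oracle_step <- function(stock, transitions, entries = NULL, aging = NULL,
                        multipliers = NULL, k = 0,
                        bands = c("under_35", "35_44", "45_54", "55_64",
                                  "65_plus")) {
  kf <- function(s, a, l, st) paste(s, a, l, st, sep = "|")
  cnt <- list()
  for (i in seq_len(nrow(stock))) {
    kk <- kf(stock$sex[i], stock$age_band[i], stock$location[i],
             stock$status[i])
    cnt[[kk]] <- (if (is.null(cnt[[kk]])) 0 else cnt[[kk]]) +
      stock$headcount[i]
  }
  getv <- function(env, kk) if (is.null(env[[kk]])) 0 else env[[kk]]

  # 1. entries
  if (!is.null(entries)) {
    al <- entries$allocation
    etab <- entries$entries
    for (i in seq_len(nrow(al))) {
      total <- sum(etab$count[etab$type == al$type[i]])
      kk <- kf(al$sex[i], al$age_band[i], al$location[i], al$status[i])
      cnt[[kk]] <- getv(cnt, kk) + total * al$fraction[i]
    }
  }

  # 2. simultaneous transition flows from the post-entry stock
  start <- cnt
  froms <- unique(transitions[, c("sex", "age_band", "from_location",
                                  "from_status")])
  for (i in seq_len(nrow(froms))) {
    sel <- transitions$sex == froms$sex[i] &
      transitions$age_band == froms$age_band[i] &
      transitions$from_location == froms$from_location[i] &
      transitions$from_status == froms$from_status[i]
    rows <- transitions[sel, ]
    m <- rep(0, nrow(rows))
    if (!is.null(multipliers)) {
      for (j in seq_len(nrow(rows))) {
        hit <- multipliers$sex == rows$sex[j] &
          multipliers$age_band == rows$age_band[j] &
          multipliers$from_location == rows$from_location[j] &
          multipliers$from_status == rows$from_status[j] &
          multipliers$to_location == rows$to_location[j] &
          multipliers$to_status == rows$to_status[j]
        if (any(hit)) m[j] <- multipliers$multiplier[which(hit)[1]]
      }
    }
    p <- pmin(pmax(rows$probability * (1 + m)^k, 0), 1)
    if (sum(p) > 1) p <- p / sum(p)
    from_key <- kf(froms$sex[i], froms$age_band[i], froms$from_location[i],
                   froms$from_status[i])
    src <- getv(start, from_key)
    for (j in seq_len(nrow(rows))) {
      flow <- src * p[j]
      to_key <- kf(rows$sex[j], rows$age_band[j], rows$to_location[j],
                   rows$to_status[j])
      cnt[[from_key]] <- getv(cnt, from_key) - flow
      cnt[[to_key]] <- getv(cnt, to_key) + flow
    }
  }

  # 3. aging of active and temporary-exit survivors
  if (!is.null(aging)) {
    snap <- cnt
    present <- bands[bands %in% unique(stock$age_band)]
    for (kk in names(snap)) {
      parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
      if (parts[4] == "permanent_exit") next
      bi <- match(parts[2], present)
      if (is.na(bi) || bi == length(present)) next
      fr <- aging$fraction[match(parts[2], aging$age_band)]
      if (is.na(fr) || fr == 0) next
      mv <- snap[[kk]] * fr
      to_key <- kf(parts[1], present[bi + 1], parts[3], parts[4])
      cnt[[kk]] <- getv(cnt, kk) - mv
      cnt[[to_key]] <- getv(cnt, to_key) + mv
    }
  }

  keys <- strsplit(names(cnt), "|", fixed = TRUE)
  tibble::tibble(
    sex = vapply(keys, `[`, "", 1),
    age_band = vapply(keys, `[`, "", 2),
    location = vapply(keys, `[`, "", 3),
    status = vapply(keys, `[`, "", 4),
    headcount = unlist(cnt, use.names = FALSE)
  )
}

# align an engine result and an oracle result for comparison
join_stocks <- function(a, b) {
  dplyr::full_join(
    a[, c("sex", "age_band", "location", "status", "headcount")],
    b[, c("sex", "age_band", "location", "status", "headcount")],
    by = c("sex", "age_band", "location", "status"),
    suffix = c("_engine", "_oracle")
  ) |>
    dplyr::mutate(
      headcount_engine = dplyr::coalesce(headcount_engine, 0),
      headcount_oracle = dplyr::coalesce(headcount_oracle, 0)
    )
}
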