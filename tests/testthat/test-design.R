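# Helpers building small design problems entirely from public API.

design_problem <- function(spec = fixture_spec()) {
  list(hosts = make_host_family(spec),
       excl = list(make_exclusion_seq(spec)),
       primer = spec$rev_primer,
       truth = fixture_truth(spec))
}

test_that("enumerate_windows emits the closed-form combination count", {
  spec <- fixture_spec()
  hosts <- make_host_family(spec)
  des <- design_blockers(hosts, NULL, spec$rev_primer)
  profile <- des$profile
  expect_length(profile$column_masks, 33L)

  # single length, single downstream offset: exactly one window
  cfg1 <- design_config(window_length_range = c(16L, 16L),
                        offset_downstream_range = c(6L, 6L))
  w1 <- enumerate_windows(profile, cfg1)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$r_start, -10L)
  expect_equal(w1$r_end, 5L)

  # closed form: for each length, offsets 0..6 all fit (L <= 27 - ...)
  cfg <- design_config()
  w <- enumerate_windows(profile, cfg)
  lens <- 14:18
  count <- sum(vapply(lens, function(L) {
    sum(vapply(0:10, function(d) {
      (d - L >= -27L) && (d - 1L <= 5L)
    }, logical(1L)))
  }, numeric(1L)))
  expect_equal(nrow(w), count)

  # brute-force nested loop gives the identical window set
  brute <- expand.grid(L = 14:18, d = 0:10)
  brute <- brute[brute$d - brute$L >= -27L & brute$d - 1L <= 5L, ]
  expect_equal(nrow(w), nrow(brute))
  key_w <- sort(paste(w$length, w$offset_downstream))
  key_b <- sort(paste(brute$L, brute$d))
  expect_equal(key_w, key_b)

  # profile shorter than the search region is a range error
  short <- conservation_profile(rand_dna(20))
  expect_error(enumerate_windows(short, cfg), "search region")
})

test_that("apply_criteria reproduces the planted criterion structure", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, pr$excl, pr$primer)
  top <- des$candidates[1L, ]
  expect_equal(top$sequence, pr$truth$window_consensus)
  expect_equal(top$host_max_mismatch, 0L)
  expect_equal(top$exclusion_min_mismatch, 3L)
  expect_equal(top$degeneracy, 1L)
  expect_true(top$pass)
  w_pos <- which(strsplit(top$sequence, "")[[1L]] == "W")
  expect_equal(w_pos, pr$truth$polymorphic_window_pos)
})

test_that("self-exclusion makes criterion 2 fail everywhere", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, pr$hosts, pr$primer)
  expect_equal(sum(des$candidates$pass), 0L)
  expect_true(all(des$candidates$exclusion_min_mismatch == 0L))
  expect_true(all(!des$candidates$crit2_exclusion))
})

test_that("an empty exclusion set flags criterion 2 as not evaluable", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, NULL, pr$primer)
  expect_true(all(is.na(des$candidates$crit2_exclusion)))
  expect_true(all(is.na(des$candidates$exclusion_min_mismatch)))
  expect_equal(sum(des$candidates$pass), 0L)
})

test_that("hosts polymorphic beyond the degeneracy cap yield no passing
           candidate", {
  withr::with_seed(41, {
    left <- rand_dna(40); interior <- rand_dna(150); right <- rand_dna(40)
    # tri-allelic columns throughout the downstream extension
    ext_variants <- c("GCAGG", "TAATG", "CGCGA", "GCAGG", "TAATG", "CGCGA")
    hosts <- lapply(seq_along(ext_variants), function(i) {
      degen_seq(build_template(left, FIX_FWD, interior,
                               paste0(FIX_REV, ext_variants[i]), right),
                id = sprintf("poly_%d", i))
    })
    excl <- list(degen_seq(build_template(left, FIX_FWD, interior,
                                          paste0(FIX_REV, "AAAAA"), right),
                 id = "excl_poly"))
    des <- design_blockers(hosts, excl, FIX_REV)
    # windows spanning three or more polymorphic columns exceed the
    # degeneracy cap and fail the host-identity criterion
    deep <- des$candidates[des$candidates$r_end >= 3L, ]
    expect_gt(nrow(deep), 0L)
    expect_true(all(!deep$crit1_host_identity))
    expect_equal(sum(des$candidates$pass), 0L)
  })
})

test_that("rank_candidates orders by the documented keys and is stable", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, pr$excl, pr$primer)
  cand <- des$candidates
  # passing first
  expect_true(all(diff(cand$pass) <= 0))
  # within the failing block, exclusion mismatches never increase
  fails <- cand[!cand$pass, ]
  excl <- ifelse(is.na(fails$exclusion_min_mismatch), -1L,
                 fails$exclusion_min_mismatch)
  expect_true(all(diff(excl) <= 0))

  # tie on all keys preserves input order (stable sort)
  two <- cand[c(2L, 3L), ]
  two$exclusion_min_mismatch <- 3L
  two$tm_metric_value <- 70
  two$selfcomp <- 2L
  two$degeneracy <- 1L
  two$r_start <- -10L
  two$pass <- TRUE
  ranked <- rank_candidates(two, design_config())
  expect_equal(ranked$sequence, two$sequence)
})

test_that("design recovery is invariant under host shuffling and monotone
           in thresholds", {
  spec <- fixture_spec(seed = 5L)
  hosts <- make_host_family(spec)
  excl <- list(make_exclusion_seq(spec))
  des <- design_blockers(hosts, excl, spec$rev_primer)
  withr::with_seed(42, {
    shuffled <- design_blockers(sample(hosts), excl, spec$rev_primer)
  })
  expect_equal(shuffled$candidates$sequence, des$candidates$sequence)
  expect_equal(shuffled$candidates$pass, des$candidates$pass)

  # raising a threshold can only shrink the passing set
  stricter <- design_blockers(hosts, excl, spec$rev_primer,
                              config = design_config(
                                min_exclusion_mismatch = 4L))
  expect_true(all(stricter$candidates$sequence[stricter$candidates$pass] %in%
                  des$candidates$sequence[des$candidates$pass]))
  hotter <- design_blockers(hosts, excl, spec$rev_primer,
                            config = design_config(tm_min = 80))
  expect_true(all(hotter$candidates$sequence[hotter$candidates$pass] %in%
                  des$candidates$sequence[des$candidates$pass]))
})

test_that("every emitted candidate matches every host with zero mismatches", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, pr$excl, pr$primer)
  expect_true(all(des$candidates$host_max_mismatch[des$candidates$pass] == 0L))
})

test_that("a missing primer site is a design error naming best counts", {
  withr::with_seed(43, {
    hosts <- list(degen_seq(rand_dna(120), id = "no_site_host"))
    expect_error(design_blockers(hosts, NULL, FIX_REV),
                 "no_site_host.*best [0-9]+ mismatches")
  })
})

test_that("candidate reports carry the coordinate convention header", {
  pr <- design_problem()
  des <- design_blockers(pr$hosts, pr$excl, pr$primer)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_report(des, f)
  lines <- readLines(f)
  expect_match(lines[1L], "coord_system")
  body <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(body), nrow(des$candidates))
  expect_true(all(body$pass %in% c(0L, 1L)))
})
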