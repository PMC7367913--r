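# Ground-truth recovery checks: run the pipeline on a generated fixture
# and compare every stage against the planted truth.

#' Randomized fixture specification for a seed
#'
#' Derives a fixture specification deterministically from a single seed,
#' varying the number of scaffolds (2-12), substituents per scaffold
#' (3-6) and planted analogous pairs; every tenth seed produces a
#' maximal-size fixture (12 scaffolds at 16 substituents, 192
#' compounds) to exercise the pipeline at scale.
#'
#' @param seed Integer seed.
#' @return A [fixture_spec()].
#' @export
random_fixture_spec <- function(seed) {
  withr::with_seed(seed, {
    if (seed %% 10L == 0L) {
      fixture_spec(
        n_scaffolds = 12L, substituents_per_scaffold = 16L,
        n_analog_pairs = 0L, seed = seed
      )
    } else {
      n_sc <- sample(2:12, 1L)
      fixture_spec(
        n_scaffolds = n_sc,
        substituents_per_scaffold = sample(3:6, 1L),
        n_analog_pairs = sample(0:(n_sc %/% 2L), 1L),
        seed = seed
      )
    }
  })
}

member_signature <- function(ids) {
  paste(sort(unique(ids), method = "radix"), collapse = ",")
}

#' Compare a pipeline run against fixture ground truth
#'
#' Checks that the pipeline recovered exactly the planted MMP pairs,
#' cliff pairs, series memberships, and series-pair relations of a
#' generated fixture. Series are compared by member sets (the planted
#' truth knows scaffolds, the pipeline reports canonical cores; member
#' sets identify both).
#'
#' @param fixture An `ac_fixture` from [generate_fixture()].
#' @param pipeline An `ac_pipeline` from [run_ac_pipeline()] on the
#'   fixture's compounds; run internally when omitted.
#' @param rules A [size_rules()] object (used when `pipeline` is `NULL`).
#' @return Named list of logicals: `mmp_ok`, `cliff_ok`, `mms_ok`,
#'   `mmsp_ok`, `all_ok`.
#' @export
check_fixture_recovery <- function(fixture, pipeline = NULL, rules = size_rules()) {
  if (is.null(pipeline)) {
    pipeline <- run_ac_pipeline(fixture$compounds, rules = rules)
  }
  truth <- fixture$truth

  got_mmp <- dplyr::arrange(
    pipeline$mmps[, c("compound_a", "compound_b")],
    .data$compound_a, .data$compound_b
  )
  mmp_ok <- isTRUE(all.equal(as.data.frame(got_mmp), as.data.frame(truth$mmp_pairs)))

  got_cliff <- dplyr::arrange(
    tibble::tibble(
      compound_a = pmin(pipeline$cliffs$high_id, pipeline$cliffs$low_id),
      compound_b = pmax(pipeline$cliffs$high_id, pipeline$cliffs$low_id)
    ),
    .data$compound_a, .data$compound_b
  )
  cliff_ok <- isTRUE(all.equal(as.data.frame(got_cliff), as.data.frame(truth$cliff_pairs)))

  got_mms <- vapply(
    pipeline$mms$members,
    function(m) member_signature(m$compound_id), character(1)
  )
  exp_mms <- vapply(truth$mms, member_signature, character(1))
  mms_ok <- identical(
    sort(unname(got_mms), method = "radix"),
    sort(unname(exp_mms), method = "radix")
  )

  sig_of_mms_id <- stats::setNames(got_mms, pipeline$mms$mms_id)
  got_mmsp <- sort(vapply(seq_len(nrow(pipeline$mmsps)), function(i) {
    s <- sort(c(
      sig_of_mms_id[[pipeline$mmsps$mms_a[i]]],
      sig_of_mms_id[[pipeline$mmsps$mms_b[i]]]
    ), method = "radix")
    paste(s, collapse = " | ")
  }, character(1)), method = "radix")
  exp_mmsp <- sort(vapply(seq_len(nrow(truth$mmsp_pairs)), function(i) {
    s <- sort(c(
      member_signature(truth$mms[[truth$mmsp_pairs$scaffold_a[i]]]),
      member_signature(truth$mms[[truth$mmsp_pairs$scaffold_b[i]]])
    ), method = "radix")
    paste(s, collapse = " | ")
  }, character(1)), method = "radix")
  mmsp_ok <- identical(got_mmsp, exp_mmsp)

  list(
    mmp_ok = mmp_ok, cliff_ok = cliff_ok, mms_ok = mms_ok, mmsp_ok = mmsp_ok,
    all_ok = mmp_ok && cliff_ok && mms_ok && mmsp_ok
  )
}
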