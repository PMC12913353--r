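#' Build the flash/beep experimental design
#'
#' Constructs the 20-condition audiovisual numerosity design: the four bimodal
#' flash/beep pairings (1F1B, 1F2B, 2F1B, 2F2B) crossed with four stimulus
#' onset asynchronies (0, 150, 300, 500 ms), plus the four unisensory
#' conditions (1F, 2F, 1B, 2B, all at SOA 0). Each condition is repeated
#' `reps` times (10 by default, giving 200 trials) and the trial order is
#' pseudorandomized with `seed`. The SOA is the onset delay between the first
#' stimulus of the leading stream and the first stimulus of the lagging
#' stream; which modality leads is fixed by `lead`. Double stimuli within a
#' stream are separated by a 50-ms inter-stimulus interval, recorded as design
#' metadata (the model uses only first onsets).
#'
#' @param lead `"visual_first"` or `"auditory_first"`: the leading modality in
#'   bimodal conditions with nonzero SOA.
#' @param reps Repetitions of each condition (>= 1).
#' @param seed Integer seed for the pseudorandom trial order.
#' @return A data frame of class `"bci_design"` with one row per trial and
#'   columns `trial_index`, `n_flashes`, `n_beeps`, `soa_ms`, `lead`.
#'   Attributes record `reps`, `lead`, `soa_set` and `isi_ms`.
#' @examples
#' d <- build_design(reps = 1)
#' nrow(d)  # 20 unique conditions
#' @export
build_design <- function(lead = c("visual_first", "auditory_first"),
                         reps = 10, seed = 1L) {
  lead <- match.arg(lead)
  stopifnot(is.numeric(reps), length(reps) == 1L, reps >= 1)
  reps <- as.integer(reps)
  soas <- c(0L, 150L, 300L, 500L)
  bim <- expand.grid(n_flashes = 1:2, n_beeps = 1:2, soa_ms = soas,
                     KEEP.OUT.ATTRS = FALSE)
  uni <- data.frame(n_flashes = c(1L, 2L, 0L, 0L),
                    n_beeps   = c(0L, 0L, 1L, 2L),
                    soa_ms    = 0L)
  conds <- rbind(bim, uni)
  trials <- conds[rep(seq_len(nrow(conds)), each = reps), , drop = FALSE]
  set.seed(seed)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials$lead <- lead
  trials <- data.frame(trial_index = seq_len(nrow(trials)), trials,
                       row.names = NULL)
  structure(trials,
            reps = reps, lead = lead, soa_set = soas, isi_ms = 50,
            seed = as.integer(seed),
            class = c("bci_design", "data.frame"))
}

#' True first-onset times implied by a bimodal condition
#'
#' The leading stream starts at 0 ms (the trial's temporal reference) and the
#' lagging stream at `soa_ms`; the `lead` flag assigns the two onsets to the
#' visual and auditory streams.
#'
#' @param n_flashes,n_beeps True stimulus counts (both must be >= 1).
#' @param soa_ms Stimulus onset asynchrony in ms.
#' @param lead Leading modality.
#' @return Named numeric vector `c(s_vt, s_at)` in ms.
#' @examples
#' true_onsets(1, 2, 500, "visual_first")
#' @export
true_onsets <- function(n_flashes, n_beeps, soa_ms,
                        lead = c("visual_first", "auditory_first")) {
  lead <- match.arg(lead)
  if (any(n_flashes < 1) || any(n_beeps < 1))
    stop("onsets are defined only for bimodal conditions", call. = FALSE)
  if (lead == "visual_first") c(s_vt = 0, s_at = as.numeric(soa_ms))
  else c(s_vt = as.numeric(soa_ms), s_at = 0)
}

# canonical condition id, used to match datasets against predictions
condition_id <- function(n_flashes, n_beeps, soa_ms) {
  sprintf("%dF%dB_soa%d", n_flashes, n_beeps, as.integer(soa_ms))
}

# unique conditions of a design/dataset, with true onsets attached
condition_table <- function(trials) {
  key <- condition_id(trials$n_flashes, trials$n_beeps, trials$soa_ms)
  u <- !duplicated(key)
  ct <- data.frame(condition = key[u],
                   n_flashes = as.integer(trials$n_flashes[u]),
                   n_beeps = as.integer(trials$n_beeps[u]),
                   soa_ms = as.integer(trials$soa_ms[u]),
                   lead = as.character(trials$lead[u]),
                   stringsAsFactors = FALSE)
  ct <- ct[order(ct$condition), , drop = FALSE]
  onset_v <- onset_a <- numeric(nrow(ct))
  for (i in seq_len(nrow(ct))) {
    if (ct$n_flashes[i] >= 1 && ct$n_beeps[i] >= 1) {
      on <- true_onsets(ct$n_flashes[i], ct$n_beeps[i], ct$soa_ms[i], ct$lead[i])
      onset_v[i] <- on[["s_vt"]]; onset_a[i] <- on[["s_at"]]
    } else {
      onset_v[i] <- 0; onset_a[i] <- 0
    }
  }
  ct$onset_v <- onset_v
  ct$onset_a <- onset_a
  ct$bimodal <- ct$n_flashes >= 1 & ct$n_beeps >= 1
  row.names(ct) <- NULL
  ct
}

#' @export
print.bci_design <- function(x, ...) {
  ct <- condition_table(x)
  cat(sprintf("Flash/beep design: %d trials, %d unique conditions, lead = %s\n",
              nrow(x), nrow(ct), attr(x, "lead")))
  cat(sprintf("  SOAs (ms): %s; reps per condition: %d; ISI: %g ms\n",
              paste(attr(x, "soa_set"), collapse = "/"), attr(x, "reps"),
              attr(x, "isi_ms")))
  invisible(x)
}
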