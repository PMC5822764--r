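#' Pair resting and post-stimulation records into response measures
#'
#' Matches each (subject, limb, side, region) key's resting acquisition
#' with its post-cuff acquisition and computes the absolute pre/post
#' differences of the digit inflow parameters: |ΔBFI|, |ΔI_max| and
#' |ΔT_rising|. Only complete pairs produce a response; unpaired keys are
#' reported alongside.
#'
#' @param records Data frame with columns `subject`, `group`, `limb`,
#'   `side`, `region`, `condition` (`"rest"`/`"post"`) and the kinetic
#'   parameter columns `bfi`, `i_max`, `t_rising` (as produced by
#'   [run_pipeline()]'s per-limb table).
#' @param limbs Limb types to pair; by default hands only (the cuff
#'   stimulus acts on the brachial artery and no lower-extremity response
#'   is expected). Use `c("hand", "foot")` to pair feet as well.
#' @param region Region whose parameters quantify the response (default
#'   `"digit"` — the fingers).
#' @return List of class `stimulus_responses`: `responses` data frame
#'   (key columns, `bfi_pre`, `bfi_post`, `abs_delta_bfi`, `imax_pre`,
#'   `imax_post`, `abs_delta_imax`, `trising_pre`, `trising_post`,
#'   `abs_delta_trising`), and `unpaired` (keys missing one condition).
#' @export
pair_conditions <- function(records, limbs = "hand", region = "digit") {
  need <- c("subject", "group", "limb", "side", "region", "condition",
            "bfi", "i_max", "t_rising")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rec <- records[records$limb %in% limbs & records$region == region, ]
  key <- interaction(rec$subject, rec$limb, rec$side, drop = TRUE)

  dup <- tapply(rec$condition, key, function(x) any(duplicated(x)))
  if (any(dup, na.rm = TRUE)) {
    stop("duplicate (key, condition) records for: ",
         paste(names(dup)[which(dup)], collapse = ", "), call. = FALSE)
  }

  pre <- rec[rec$condition == "rest", ]
  post <- rec[rec$condition == "post", ]
  kcols <- c("subject", "group", "limb", "side")
  merged <- merge(pre, post, by = kcols, suffixes = c("_pre", "_post"))
  responses <- data.frame(
    merged[kcols], region = rep(region, nrow(merged)),
    bfi_pre = merged$bfi_pre, bfi_post = merged$bfi_post,
    abs_delta_bfi = abs(merged$bfi_post - merged$bfi_pre),
    imax_pre = merged$i_max_pre, imax_post = merged$i_max_post,
    abs_delta_imax = abs(merged$i_max_post - merged$i_max_pre),
    trising_pre = merged$t_rising_pre, trising_post = merged$t_rising_post,
    abs_delta_trising = abs(merged$t_rising_post - merged$t_rising_pre),
    stringsAsFactors = FALSE)

  all_keys <- unique(rec[kcols])
  paired <- interaction(responses[kcols], drop = TRUE)
  unpaired <- all_keys[!interaction(all_keys, drop = TRUE) %in% paired, ]
  structure(list(responses = responses, unpaired = unpaired),
            class = "stimulus_responses")
}

#' @export
print.stimulus_responses <- function(x, ...) {
  cat(sprintf("<stimulus_responses> %d pairs (%d unpaired keys)\n",
              nrow(x$responses), nrow(x$unpaired)))
  invisible(x)
}

#' Pre-vs-post scatter table with identity-line distance
#'
#' Table behind the pre/post BFI scatter against the y = x line: a
#' non-responding limb sits on the identity line, so its perpendicular
#' distance |post - pre| / sqrt(2) is zero.
#'
#' @param responses A `stimulus_responses` object or its `responses`
#'   data frame.
#' @return Data frame with `group`, `bfi_pre`, `bfi_post` and
#'   `identity_distance`.
#' @export
response_scatter <- function(responses) {
  if (inherits(responses, "stimulus_responses")) responses <- responses$responses
  if (nrow(responses) == 0L) stop("no responses to tabulate", call. = FALSE)
  data.frame(group = responses$group,
             subject = responses$subject,
             side = responses$side,
             bfi_pre = responses$bfi_pre,
             bfi_post = responses$bfi_post,
             identity_distance = abs(responses$bfi_post - responses$bfi_pre) / sqrt(2),
             stringsAsFactors = FALSE)
}
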