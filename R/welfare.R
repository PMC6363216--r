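#' Build an observation stream
#'
#' A per-horse record of the behavioural observations needed by the scoring
#' rules: the time-ordered stereotypy/abnormal-repetitive-behaviour events
#' (each a behaviour label with the number of successive repeats of its
#' sequence), exactly 10 instantaneous ear-position scans taken while
#' foraging, the number of sightings of the depressed-like posture, and the
#' observation duration.
#'
#' @param horse_id identifier.
#' @param events data frame with columns `label` and `run_length`
#'   (successive repeats, >= 1); may have zero rows.
#' @param ear_scans character vector of length 10 with values `"forward"`,
#'   `"backward"`, `"neutral"`.
#' @param depressed_seen count of depressed-like posture sightings.
#' @param total_hours observation duration (metadata only; the scoring rules
#'   are independent of the period of observation).
#' @return An object of class `observation_stream`.
#' @export
observation_stream <- function(horse_id, events = NULL, ear_scans,
                               depressed_seen = 0, total_hours = 18) {
  if (is.null(events)) {
    events <- data.frame(label = character(0), run_length = integer(0))
  }
  events <- as.data.frame(events)
  stopifnot(all(c("label", "run_length") %in% names(events)))
  if (nrow(events) && any(events$run_length < 1)) {
    stop("run_length must be >= 1", call. = FALSE)
  }
  ear_scans <- as.character(ear_scans)
  if (length(ear_scans) != 10) {
    stop("ear_scans must have exactly 10 entries (got ", length(ear_scans), ")",
         call. = FALSE)
  }
  if (!all(ear_scans %in% c("forward", "backward", "neutral"))) {
    stop("ear scans must be 'forward', 'backward' or 'neutral'", call. = FALSE)
  }
  structure(list(horse_id = horse_id, events = events, ear_scans = ear_scans,
                 depressed_seen = as.integer(depressed_seen),
                 total_hours = total_hours),
            class = "observation_stream")
}

#' Score stereotypic / abnormal repetitive behaviour
#'
#' A horse scores 1 when some behaviour was observed as at least 5 events,
#' each consisting of at least 3 successive repeats of the sequence,
#' independently of the observation period; 0 otherwise. The score is
#' monotone: adding events never turns a 1 into a 0.
#'
#' @param stream an [observation_stream()].
#' @return 0 or 1.
#' @export
#' @examples
#' ev <- data.frame(label = "weaving", run_length = c(3, 4, 3, 5, 3))
#' score_sb_arb(observation_stream("h1", ev, rep("neutral", 10)))
score_sb_arb <- function(stream) {
  stopifnot(inherits(stream, "observation_stream"))
  ev <- stream$events
  if (!nrow(ev)) return(0L)
  qualifying <- ev[ev$run_length >= 3, , drop = FALSE]
  if (!nrow(qualifying)) return(0L)
  as.integer(max(table(qualifying$label)) >= 5)
}

#' Score the depressed-like posture
#'
#' Binary: 1 when the characteristic immobile, flat-necked,
#' environment-indifferent posture was seen at least once during the
#' observation time, 0 otherwise.
#'
#' @param stream an [observation_stream()].
#' @return 0 or 1.
#' @export
score_depressed <- function(stream) {
  stopifnot(inherits(stream, "observation_stream"))
  as.integer(stream$depressed_seen >= 1)
}

#' Categorize the favourite ear position
#'
#' Over exactly 10 instantaneous scans a horse is assigned its favourite
#' posture when one category reaches at least 60% of the scans: `"forward"`
#' or `"backward"`; otherwise `"neutral"` (asymmetric/lateral positions are
#' counted as neutral). At most one category can reach 60%, so a 5/5 split is
#' neutral.
#'
#' @param scans character vector of 10 scans (`"forward"`, `"backward"`,
#'   `"neutral"`) or an [observation_stream()].
#' @return `"forward"`, `"backward"` or `"neutral"`.
#' @export
categorize_ear_position <- function(scans) {
  if (inherits(scans, "observation_stream")) scans <- scans$ear_scans
  if (length(scans) != 10) {
    stop("exactly 10 ear scans required (got ", length(scans), ")", call. = FALSE)
  }
  if (sum(scans == "forward") >= 6) return("forward")
  if (sum(scans == "backward") >= 6) return("backward")
  "neutral"
}

#' Prevalence of a binary indicator
#'
#' The percentage of individuals flagged 1, reported both raw and rounded to
#' the nearest integer percent (half-up), the style used when prevalences are
#' printed as "N (%)".
#'
#' @param flags vector of 0/1 (or logical).
#' @return list with `n` (count of 1s), `total`, `raw` (exact percentage) and
#'   `rounded` (integer percent, half-up).
#' @export
#' @examples
#' prevalence(c(rep(1, 15), rep(0, 70)))$rounded # 18
prevalence <- function(flags) {
  if (length(flags) == 0) stop("empty indicator vector", call. = FALSE)
  flags <- as.integer(as.logical(flags))
  raw <- 100 * sum(flags) / length(flags)
  list(n = sum(flags), total = length(flags), raw = raw,
       rounded = floor(raw + 0.5))
}

welfare_columns <- c("horse_id", "sb_arb", "depressed", "ear_category",
                     "type_of_equid", "proportion", "hay_meals",
                     "paddock_time", "paddock_social", "visible_conspecifics",
                     "work_hours")

#' Read / write per-horse welfare record tables
#'
#' Plain CSV with one row per horse: binary `sb_arb` and `depressed`,
#' `ear_category` (forward/backward/neutral) and the management covariates
#' `type_of_equid` (pony/horse), `proportion` (dolicho/meso/brachy),
#' `hay_meals`, `paddock_time` (percent), `paddock_social` (alone/group),
#' `visible_conspecifics`, `work_hours` (per week).
#'
#' @param path CSV path.
#' @return `read_welfare_csv`: a data frame with the columns above.
#' @export
read_welfare_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("horse_id", "sb_arb", "depressed", "ear_category"), names(df))
  if (length(missing)) {
    stop("welfare table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$sb_arb %in% 0:1) || !all(df$depressed %in% 0:1)) {
    stop("sb_arb and depressed must be binary 0/1", call. = FALSE)
  }
  df
}

#' @param records data frame of welfare records.
#' @rdname read_welfare_csv
#' @export
write_welfare_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read / write observation streams as long CSV
#'
#' A tidy long format with columns `horse_id`, `kind`
#' (`event`/`ear_scan`/`depressed`/`hours`), `index`, `label`, `value`:
#' events carry label + run length, ear scans carry the scan position and
#' category, the depressed row the sighting count and the hours row the
#' observation duration.
#'
#' @param streams list of [observation_stream()].
#' @param path CSV path.
#' @return `read_streams_csv`: list of [observation_stream()].
#' @export
write_streams_csv <- function(streams, path) {
  rows <- lapply(streams, function(s) {
    ev <- if (nrow(s$events)) {
      data.frame(horse_id = s$horse_id, kind = "event",
                 index = seq_len(nrow(s$events)),
                 label = s$events$label, value = s$events$run_length)
    }
    rbind(
      ev,
      data.frame(horse_id = s$horse_id, kind = "ear_scan", index = 1:10,
                 label = s$ear_scans, value = NA_real_),
      data.frame(horse_id = s$horse_id, kind = "depressed", index = 1L,
                 label = "", value = s$depressed_seen),
      data.frame(horse_id = s$horse_id, kind = "hours", index = 1L,
                 label = "", value = s$total_hours)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_streams_csv
#' @export
read_streams_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$horse_id)[unique(df$horse_id)], function(d) {
    ev <- d[d$kind == "event", , drop = FALSE]
    observation_stream(
      horse_id = d$horse_id[1],
      events = data.frame(label = ev$label, run_length = ev$value),
      ear_scans = d$label[d$kind == "ear_scan"][order(d$index[d$kind == "ear_scan"])],
      depressed_seen = d$value[d$kind == "depressed"][1],
      total_hours = d$value[d$kind == "hours"][1]
    )
  })
}
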