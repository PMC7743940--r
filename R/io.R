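BEHAVIORS <- c("wing_extension", "lunge", "headbutt")
PAIR_TYPES <- c("male_male", "male_female", "female_female", "other")

ANNOTATION_COLS <- c("movie_id", "fly_id", "behavior", "observer_id",
                     "start_frame", "end_frame", "confidence")
SCORE_COLS <- c("movie_id", "fly_id", "behavior", "frame", "score")
MOVIE_COLS <- c("movie_id", "pair_type", "fps", "n_frames", "role", "wells")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(...) {
  stop(structure(class = c("ethobench_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_value <- function(...) {
  stop(structure(class = c("ethobench_value_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_schema(what, ": missing required column(s): ",
                paste(missing, collapse = ", "))
  invisible(df)
}

read_tabular <- function(path, dialect = c("csv", "xlsx"), sheet = NULL,
                         column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_value("file does not exist: ", path)
  df <- if (dialect == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_value("reading xlsx requires the 'readxl' package; ",
                 "export the table to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = sheet %||% 1L),
                  stringsAsFactors = FALSE)
  }
  if (!is.null(column_map)) {
    # column_map: named character, names = canonical, values = as-on-disk
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df))
        stop_schema(path, ": mapped column '", src, "' (for '", canonical,
                    "') not found")
      names(df)[names(df) == src] <- canonical
    }
  }
  df
}

#' Read per-observer bout annotations
#'
#' Ingests a table of human bout annotations: one row per bout with a 1-3
#' confidence grade ("maybe" = 1, "probably" = 2, "definitely" = 3), the
#' structure produced by exporting per-observer annotation tables to CSV or
#' XLSX. Frame intervals are 1-based and inclusive; a `frame_base = 0` input
#' is shifted up by one on ingest.
#'
#' @param path Path to a CSV or XLSX file with columns `movie_id`, `fly_id`,
#'   `behavior`, `observer_id`, `start_frame`, `end_frame`, `confidence`
#'   (or columns mapped onto these via `column_map`).
#' @param dialect `"csv"` (default) or `"xlsx"`.
#' @param movies Optional movie metadata (from [read_movies()]); when given,
#'   frame indices are validated against each movie's `n_frames`.
#' @param frame_base Either 1 (default; frames already 1-based) or 0
#'   (0-based input, converted to 1-based).
#' @param merge_observer_overlaps Same-observer overlapping bouts signal
#'   corrupted input and raise an error by default; set `TRUE` to instead
#'   merge them, keeping the maximum confidence.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used on disk, e.g. `c(start_frame = "Start")`.
#' @param sheet XLSX sheet name or index.
#' @return A `data.frame` of validated observer bouts, row order preserved.
#' @seealso [read_scores()], [read_movies()], [write_table()]
#' @export
read_annotations <- function(path, dialect = c("csv", "xlsx"), movies = NULL,
                             frame_base = 1L, merge_observer_overlaps = FALSE,
                             column_map = NULL, sheet = NULL) {
  df <- read_tabular(path, dialect, sheet = sheet, column_map = column_map)
  as_annotations(df, movies = movies, frame_base = frame_base,
                 merge_observer_overlaps = merge_observer_overlaps)
}

#' Validate an in-memory annotation table
#'
#' @param df A data.frame with the [read_annotations()] columns.
#' @inheritParams read_annotations
#' @return The validated (and possibly overlap-merged) data.frame.
#' @export
as_annotations <- function(df, movies = NULL, frame_base = 1L,
                           merge_observer_overlaps = FALSE) {
  check_columns(df, ANNOTATION_COLS, "annotations")
  df <- df[, ANNOTATION_COLS]
  for (col in c("movie_id", "fly_id", "behavior", "observer_id"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("start_frame", "end_frame", "confidence")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != as.integer(v)))
      stop_value("annotations: column '", col, "' must be whole numbers ",
                 "(first bad row: ",
                 which(!is.finite(suppressWarnings(as.numeric(v))) |
                         v != suppressWarnings(as.integer(v)))[1], ")")
    df[[col]] <- as.integer(v)
  }
  if (!frame_base %in% c(0L, 1L)) stop_value("frame_base must be 0 or 1")
  if (frame_base == 0L) {
    df$start_frame <- df$start_frame + 1L
    df$end_frame <- df$end_frame + 1L
  }
  bad <- which(!df$confidence %in% 1:3)
  if (length(bad) > 0L)
    stop_value("annotations row ", bad[1], ": confidence ",
               df$confidence[bad[1]], " outside the 1-3 scale ",
               "(1 = maybe, 2 = probably, 3 = definitely)")
  bad <- which(df$start_frame > df$end_frame)
  if (length(bad) > 0L)
    stop_value("annotations row ", bad[1], ": start_frame ",
               df$start_frame[bad[1]], " > end_frame ", df$end_frame[bad[1]])
  bad <- which(df$start_frame < 1L)
  if (length(bad) > 0L)
    stop_value("annotations row ", bad[1], ": start_frame < 1")
  bad <- which(!df$behavior %in% BEHAVIORS)
  if (length(bad) > 0L)
    stop_value("annotations row ", bad[1], ": unknown behavior '",
               df$behavior[bad[1]], "' (expected one of: ",
               paste(BEHAVIORS, collapse = ", "), ")")
  if (!is.null(movies)) {
    idx <- match(df$movie_id, movies$movie_id)
    if (anyNA(idx))
      stop_value("annotations row ", which(is.na(idx))[1],
                 ": movie_id not present in movie metadata")
    bad <- which(df$end_frame > movies$n_frames[idx])
    if (length(bad) > 0L)
      stop_value("annotations row ", bad[1], ": end_frame ",
                 df$end_frame[bad[1]], " exceeds movie n_frames ",
                 movies$n_frames[idx[bad[1]]])
  }
  df <- resolve_same_observer_overlaps(df, merge_observer_overlaps)
  rownames(df) <- NULL
  df
}

# Same-observer overlaps: error in strict mode, otherwise merge keeping the
# maximum confidence (annotation tools prevent overlaps, so overlap usually
# signals corrupted input).
resolve_same_observer_overlaps <- function(df, merge) {
  if (nrow(df) < 2L) return(df)
  key <- interaction(df$movie_id, df$fly_id, df$behavior, df$observer_id,
                     drop = TRUE)
  pieces <- split(seq_len(nrow(df)), key)
  drop <- integer(0)
  for (rows in pieces) {
    if (length(rows) < 2L) next
    o <- rows[order(df$start_frame[rows], df$end_frame[rows])]
    repeat {
      s <- df$start_frame[o]; e <- df$end_frame[o]
      ov <- which(s[-1] <= e[-length(e)])
      if (length(ov) == 0L) break
      if (!merge)
        stop_value("annotations: observer '", df$observer_id[o[1]],
                   "' has overlapping bouts at rows ", o[ov[1]], " and ",
                   o[ov[1] + 1L],
                   " (same movie/fly/behavior); pass ",
                   "merge_observer_overlaps = TRUE to union them")
      i <- ov[1]
      df$end_frame[o[i]] <- max(e[i], e[i + 1L])
      df$confidence[o[i]] <- max(df$confidence[o[i]], df$confidence[o[i + 1L]])
      drop <- c(drop, o[i + 1L])
      o <- o[-(i + 1L)]
    }
  }
  if (length(drop) > 0L) df <- df[-drop, , drop = FALSE]
  df
}

#' Read per-frame classifier score tracks
#'
#' Ingests long-format per-frame classifier confidence scores (one real
#' number per frame per fly per behavior, the shape of JAABA per-frame
#' output exported to CSV) and assembles one score track per
#' (movie, fly, behavior). Frames must be contiguous from 1.
#'
#' @inheritParams read_annotations
#' @param path CSV with columns `movie_id`, `fly_id`, `behavior`, `frame`,
#'   `score`.
#' @return A `data.frame` with one row per track and columns `movie_id`,
#'   `fly_id`, `behavior`, `n_frames` and a list-column `scores` holding the
#'   numeric per-frame score vector.
#' @export
read_scores <- function(path, dialect = c("csv", "xlsx"), frame_base = 1L,
                        column_map = NULL, sheet = NULL) {
  df <- read_tabular(path, dialect, sheet = sheet, column_map = column_map)
  as_score_tracks(df, frame_base = frame_base)
}

#' Assemble score tracks from a long-format table
#'
#' @param df Long-format data.frame (`movie_id`, `fly_id`, `behavior`,
#'   `frame`, `score`).
#' @inheritParams read_annotations
#' @return One-row-per-track data.frame with list-column `scores`.
#' @export
as_score_tracks <- function(df, frame_base = 1L) {
  check_columns(df, SCORE_COLS, "scores")
  if (!frame_base %in% c(0L, 1L)) stop_value("frame_base must be 0 or 1")
  if (frame_base == 0L) df$frame <- df$frame + 1L
  if (!is.numeric(df$score) || any(!is.finite(df$score)))
    stop_value("scores: non-finite score at row ",
               which(!is.finite(suppressWarnings(as.numeric(df$score))))[1])
  key <- interaction(df$movie_id, df$fly_id, df$behavior, drop = TRUE)
  pieces <- split(seq_len(nrow(df)), key)
  out <- lapply(pieces, function(rows) {
    sub <- df[rows, ]
    sub <- sub[order(sub$frame), ]
    fr <- sub$frame
    expect <- seq_len(length(fr))
    if (!identical(as.integer(fr), as.integer(expect))) {
      miss <- setdiff(expect, fr)
      if (length(miss) > 0L)
        stop_value("scores for (", sub$movie_id[1], ", ", sub$fly_id[1], ", ",
                   sub$behavior[1], "): frames not contiguous from 1; ",
                   "first missing frame: ", miss[1])
      stop_value("scores for (", sub$movie_id[1], ", ", sub$fly_id[1], ", ",
                 sub$behavior[1], "): duplicated frame ",
                 fr[which(duplicated(fr))[1]])
    }
    list(movie_id = sub$movie_id[1], fly_id = sub$fly_id[1],
         behavior = sub$behavior[1], n_frames = length(fr),
         scores = list(as.numeric(sub$score)))
  })
  tracks <- do.call(rbind, lapply(out, function(x)
    data.frame(movie_id = x$movie_id, fly_id = x$fly_id,
               behavior = x$behavior, n_frames = x$n_frames,
               stringsAsFactors = FALSE)))
  tracks$scores <- lapply(out, function(x) x$scores[[1]])
  rownames(tracks) <- NULL
  tracks[order(tracks$movie_id, tracks$fly_id, tracks$behavior), ,
         drop = FALSE]
}

#' Normalize a pair-type label
#'
#' Maps the sex-combination labels used in movie inventories (unicode
#' "male vs. male" style symbols, `MM`/`MF`/`FF` codes, or the canonical
#' names) onto `male_male`, `male_female`, `female_female`, `other`.
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical pair types.
#' @export
normalize_pair_type <- function(x) {
  raw <- x
  x <- tolower(trimws(as.character(x)))
  x <- gsub("♂", "m", x, fixed = TRUE)
  x <- gsub("♀", "f", x, fixed = TRUE)
  x <- gsub("[[:space:].]|vs", "", x)
  out <- character(length(x))
  out[x %in% c("mm", "male_male", "malemale")] <- "male_male"
  out[x %in% c("mf", "fm", "male_female", "malefemale")] <- "male_female"
  out[x %in% c("ff", "female_female", "femalefemale")] <- "female_female"
  out[startsWith(x, "other")] <- "other"
  bad <- which(out == "")
  if (length(bad) > 0L)
    stop_value("unknown pair type '", raw[bad[1]], "'; accepted values: ",
               "male vs. male / MM / male_male, male vs. female / MF, ",
               "female vs. female / FF, other")
  out
}

#' Read movie metadata
#'
#' Ingests the movie inventory: one row per movie with its sex combination
#' (pair type), frame rate, length in frames, and whether the movie served
#' for classifier training or for evaluation against human annotation.
#'
#' @inheritParams read_annotations
#' @param path CSV with columns `movie_id`, `pair_type`, `fps`, `n_frames`,
#'   `role`, `wells` (wells semicolon-separated; may be empty).
#' @return Validated movie metadata `data.frame`; `wells` is a list-column.
#' @export
read_movies <- function(path, dialect = c("csv", "xlsx"), column_map = NULL,
                        sheet = NULL) {
  df <- read_tabular(path, dialect, sheet = sheet, column_map = column_map)
  as_movies(df)
}

#' Validate an in-memory movie metadata table
#' @param df data.frame with at least `movie_id`, `pair_type`, `n_frames`.
#' @return Validated data.frame with canonical pair types.
#' @export
as_movies <- function(df) {
  check_columns(df, c("movie_id", "pair_type", "n_frames"), "movies")
  df$movie_id <- as.character(df$movie_id)
  if (anyDuplicated(df$movie_id))
    stop_value("movies: duplicated movie_id '",
               df$movie_id[anyDuplicated(df$movie_id)], "'")
  df$pair_type <- normalize_pair_type(df$pair_type)
  if (is.null(df$fps) || all(is.na(df$fps))) {
    message("movies: fps not provided; defaulting to 60 frames/second")
    df$fps <- 60
  }
  df$fps[is.na(df$fps)] <- 60
  if (any(df$fps <= 0)) stop_value("movies: fps must be > 0")
  if (any(is.na(df$n_frames) | df$n_frames < 1))
    stop_value("movies: n_frames must be >= 1")
  df$n_frames <- as.integer(df$n_frames)
  if (is.null(df$role)) df$role <- "evaluation"
  df$role <- tolower(as.character(df$role))
  if (!all(df$role %in% c("training", "evaluation")))
    stop_value("movies: role must be 'training' or 'evaluation'")
  if (is.null(df$wells)) df$wells <- ""
  if (!is.list(df$wells))
    df$wells <- lapply(strsplit(as.character(df$wells), ";", fixed = TRUE),
                       trimws)
  df[, MOVIE_COLS]
}

#' Write a result table to CSV
#'
#' Writes any of the package's tabular results (annotations, tracks in long
#' format, combined bouts, classifier bouts, match records, metrics rows)
#' as UTF-8 CSV with a stable column order. List-columns (score records,
#' classifier references, wells) are flattened by semicolon-joining; the
#' corresponding readers re-split them, so read-write round-trips are the
#' identity on valid tables.
#'
#' @param records A data.frame (possibly with list-columns).
#' @param path Output file path.
#' @return Invisibly, the flattened data.frame written.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop_value("write_table expects a data.frame")
  flat <- records
  for (col in names(flat)) {
    if (col == "scores" && is.list(flat[[col]])) {
      # expand score tracks back to long format
      return(write_table(tracks_to_long(records), path))
    }
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]],
                            function(v) paste(v, collapse = ";"), "")
  }
  ok <- tryCatch({
    utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_value("cannot write '", path, "': ",
                              conditionMessage(ok))
  invisible(flat)
}

#' Expand score tracks to long format
#' @param tracks Track table from [read_scores()] / [as_score_tracks()].
#' @return Long data.frame (`movie_id`, `fly_id`, `behavior`, `frame`,
#'   `score`).
#' @export
tracks_to_long <- function(tracks) {
  n <- vapply(tracks$scores, length, 0L)
  data.frame(
    movie_id = rep(tracks$movie_id, n),
    fly_id = rep(tracks$fly_id, n),
    behavior = rep(tracks$behavior, n),
    frame = unlist(lapply(n, seq_len), use.names = FALSE),
    score = unlist(tracks$scores, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# shared helper: select one (movie, fly, behavior) track's score vector
track_scores <- function(tracks, movie_id, fly_id, behavior) {
  i <- which(tracks$movie_id == movie_id & tracks$fly_id == fly_id &
               tracks$behavior == behavior)
  if (length(i) != 1L)
    stop_value("expected exactly one score track for (", movie_id, ", ",
               fly_id, ", ", behavior, "); found ", length(i))
  tracks$scores[[i]]
}
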