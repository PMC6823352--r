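#' Create a hypnogram
#'
#' A hypnogram is the per-epoch time series of vigilance-stage labels
#' (WAKE/NREM/REM), optionally with per-stage certainties.  It is stored as
#' a tibble with 0-based `epoch` indices so it joins naturally against
#' prediction tables.
#'
#' @param stages Stage labels: factor/character (`"W"/"N"/"R"` or full names,
#'   case-insensitive) or integer codes 1..3.
#' @param certainties Optional numeric matrix (n x 3) of per-stage
#'   probabilities; each row must be non-negative, sum to 1 (±1e-6), and its
#'   argmax (ties broken WAKE < NREM < REM) must match the stored label.
#' @param record_id Identifier of the scored record.
#' @param epoch_length Epoch duration in seconds.
#' @return A `hypnogram` tibble with columns `epoch`, `stage` and, when
#'   certainties are given, `p_wake`, `p_nrem`, `p_rem`.
#' @examples
#' hypnogram(c("W", "W", "N", "R"))
#' @export
hypnogram <- function(stages, certainties = NULL, record_id = "record",
                      epoch_length = 20) {
  stage <- stage_factor(stages)
  out <- tibble(epoch = seq_along(stage) - 1L, stage = stage)
  if (!is.null(certainties)) {
    certainties <- as.matrix(certainties)
    if (nrow(certainties) != length(stage) || ncol(certainties) != 3) {
      abort("certainties must be an n x 3 matrix aligned with stages")
    }
    if (any(certainties < 0)) abort("certainties must be non-negative")
    if (any(abs(rowSums(certainties) - 1) > 1e-6)) {
      abort("certainty rows must sum to 1 (tolerance 1e-6)")
    }
    am <- apply(certainties, 1, which.max)
    if (any(am != as.integer(stage))) {
      abort("certainty argmax disagrees with stored stage label")
    }
    out$p_wake <- certainties[, 1]
    out$p_nrem <- certainties[, 2]
    out$p_rem <- certainties[, 3]
  }
  attr(out, "record_id") <- as.character(record_id)
  attr(out, "epoch_length") <- epoch_length
  class(out) <- c("hypnogram", class(out))
  out
}

#' Stage labels of a hypnogram or prediction table as a factor
#' @param x A `hypnogram`, prediction tibble, factor or character vector.
#' @return Factor with levels WAKE, NREM, REM.
#' @export
stages_of <- function(x) {
  if (is.data.frame(x)) stage_factor(x$stage) else stage_factor(x)
}

#' Read / write hypnogram TSV files
#'
#' The on-disk dialect is tab-separated with columns `epoch_index`, `stage`
#' (single letters `W`/`N`/`R`; `U` marks unscored epochs on read) and
#' optional `p_wake`, `p_nrem`, `p_rem` written to 6 decimals, preceded by
#' `#` comment lines carrying the record id and epoch length.
#'
#' @param x A `hypnogram`.
#' @param path File path.
#' @return `read_hypnogram()` returns a `hypnogram` (unscored `U` rows are
#'   dropped, preserving their epoch indices in the remaining rows);
#'   `write_hypnogram()` returns the path invisibly.
#' @export
write_hypnogram <- function(x, path) {
  stopifnot(inherits(x, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id: %s", attr(x, "record_id") %||% "record"),
               sprintf("# epoch_length: %g", attr(x, "epoch_length") %||% 20)),
             con)
  has_p <- all(c("p_wake", "p_nrem", "p_rem") %in% names(x))
  if (has_p) {
    writeLines("epoch_index\tstage\tp_wake\tp_nrem\tp_rem", con)
    # write 6-decimal certainties that still sum exactly to 1: the REM
    # column absorbs the rounding of the first two (and any deficit is
    # taken from the NREM column so no value goes negative)
    pw <- round(x$p_wake, 6)
    pn <- round(x$p_nrem, 6)
    pr <- round(1 - pw - pn, 6)
    neg <- pr < 0
    pn[neg] <- pn[neg] + pr[neg]
    pr[neg] <- 0
    writeLines(sprintf("%d\t%s\t%.6f\t%.6f\t%.6f", x$epoch,
                       STAGE_LETTERS[as.integer(x$stage)],
                       pw, pn, pr), con)
  } else {
    writeLines("epoch_index\tstage", con)
    writeLines(sprintf("%d\t%s", x$epoch,
                       STAGE_LETTERS[as.integer(x$stage)]), con)
  }
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(m) == 0) default else trimws(sub("^[^:]*:", "", m[1]))
  }
  record_id <- get_meta("record_id", "record")
  epoch_length <- as.numeric(get_meta("epoch_length", "20"))

  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) == 0) abort("empty hypnogram file")
  header <- strsplit(lines[body_idx[1]], "\t")[[1]]
  simple <- length(header) == 1 || !identical(header[1], "epoch_index")
  data_idx <- if (simple) body_idx else body_idx[-1]

  fields <- strsplit(lines[data_idx], "\t")
  ncols <- lengths(fields)
  if (simple) {
    tokens <- vapply(fields, `[`, character(1), 1)
    epoch <- seq_along(tokens) - 1L
    probs <- NULL
  } else {
    epoch <- as.integer(vapply(fields, `[`, character(1), 1))
    tokens <- vapply(fields, `[`, character(1), 2)
    probs <- if (all(ncols >= 5)) {
      matrix(as.numeric(unlist(lapply(fields, `[`, 3:5))),
             ncol = 3, byrow = TRUE)
    }
  }
  keep <- toupper(tokens) != "U"
  for (i in which(!vapply(tokens[keep], function(tk) {
    toupper(tk) %in% c("W", "N", "R", "WAKE", "NREM", "NON-REM", "NONREM", "REM")
  }, logical(1)))) {
    abort(sprintf("unknown stage token '%s' at line %d of %s",
                  tokens[keep][i], data_idx[keep][i], path))
  }
  h <- hypnogram(tokens[keep], certainties = if (!is.null(probs)) probs[keep, , drop = FALSE],
                 record_id = record_id, epoch_length = epoch_length)
  h$epoch <- epoch[keep]
  h
}
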