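#' Construct a visit
#'
#' A visit is one healthcare encounter: a set of event codes (stored as
#' 1-based indices into the corpus vocabulary), with optional day offset,
#' location, binary readmission label and admission duration.
#'
#' @param codes integer vector of vocabulary indices (duplicates collapsed).
#' @param time optional integer day offset from the patient's first visit.
#' @param loc optional location category, e.g. "inpatient" or "outpatient".
#' @param label optional binary readmission label (0/1).
#' @param duration optional non-negative admission length in days.
#' @return a list of class \code{ehr_visit}.
#' @export
ehr_visit <- function(codes = integer(), time = NULL, loc = NULL,
                      label = NULL, duration = NULL) {
  codes <- sort(unique(as.integer(codes)))
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% c(0L, 1L)) stop("visit label must be 0 or 1")
  }
  if (!is.null(duration) && duration < 0) stop("duration must be non-negative")
  structure(list(codes = codes, time = if (is.null(time)) NULL else as.integer(time),
                 loc = loc, label = label,
                 duration = if (is.null(duration)) NULL else as.integer(duration)),
            class = "ehr_visit")
}

#' Construct a patient record
#'
#' @param pid patient identifier string.
#' @param visits list of \code{\link{ehr_visit}} objects, in chronological order.
#' @param mask logical vector, one entry per visit: \code{TRUE} where the visit
#'   carries a supervised label. Defaults to \code{TRUE} exactly where a label
#'   is present.
#' @return a list of class \code{ehr_record}.
#' @export
ehr_record <- function(pid, visits, mask = NULL) {
  if (length(visits) < 1) stop("a patient record needs at least one visit")
  if (is.null(mask)) mask <- vapply(visits, function(v) !is.null(v$label), logical(1))
  if (length(mask) != length(visits)) stop("mask length must equal number of visits")
  has_lab <- vapply(visits, function(v) !is.null(v$label), logical(1))
  if (any(mask & !has_lab)) stop("masked-in visits must carry a label")
  tms <- unlist(lapply(visits, function(v) v$time))
  if (length(tms) == length(visits) && is.unsorted(tms)) {
    stop("visit times must be non-decreasing for patient ", pid)
  }
  structure(list(pid = as.character(pid), visits = visits, mask = as.logical(mask)),
            class = "ehr_record")
}

#' Construct an EHR corpus
#'
#' The corpus bundles a fixed code vocabulary with a list of patient records
#' and an optional train/validation/test split tag per record.
#'
#' @param vocab character vector of distinct code strings; index i corresponds
#'   to code \code{vocab[i]}.
#' @param records list of \code{\link{ehr_record}} objects.
#' @param split optional character vector (one of "train", "validation",
#'   "test") per record.
#' @return an object of class \code{ehr_corpus}.
#' @export
ehr_corpus <- function(vocab, records, split = NULL) {
  vocab <- as.character(vocab)
  if (anyDuplicated(vocab)) stop("vocabulary contains duplicate codes")
  C <- length(vocab)
  for (r in records) {
    for (v in r$visits) {
      if (length(v$codes) && (min(v$codes) < 1L || max(v$codes) > C)) {
        stop("record ", r$pid, " uses a code index outside the vocabulary")
      }
    }
  }
  if (!is.null(split)) {
    if (length(split) != length(records)) stop("split must tag every record")
    bad <- setdiff(unique(split[!is.na(split)]), c("train", "validation", "test"))
    if (length(bad)) stop("unknown split tag: ", paste(bad, collapse = ", "))
  }
  structure(list(vocab = vocab, records = records, split = split),
            class = "ehr_corpus")
}

#' @export
print.ehr_corpus <- function(x, ...) {
  cat("EHR corpus:", length(x$records), "patients,",
      length(x$vocab), "codes in vocabulary\n")
  if (!is.null(x$split)) {
    tb <- table(factor(x$split, levels = c("train", "validation", "test")))
    cat("  split:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.ehr_record <- function(x, ...) {
  cat("patient", x$pid, "-", length(x$visits), "visits,",
      sum(x$mask), "supervised\n")
  invisible(x)
}

n_visits <- function(record) length(record$visits)

#' Read a visit-sequence corpus
#'
#' Two dialects are supported. \code{"jsonl"} is the canonical format: JSON
#' Lines, one patient per line,
#' \code{{"pid": str, "visits": [{"t": int|null, "loc": str|null,
#' "codes": [str], "label": 0|1|null}]}}. \code{"flat"} is a compact
#' tab-separated format for pre-labeled corpora without timestamps: one
#' patient per line, \code{pid<TAB>visit;visit;...} where each visit is
#' \code{label,code code code} and \code{label} may be \code{-} for
#' unlabeled.
#'
#' @param path input file path.
#' @param dialect "jsonl" or "flat".
#' @param vocab optional fixed vocabulary (character vector or path to a file
#'   with one code per line). When supplied, an unknown code is an error;
#'   otherwise the vocabulary is built from all codes seen, in order of first
#'   appearance.
#' @return an \code{\link{ehr_corpus}}.
#' @export
read_ehr_corpus <- function(path, dialect = c("jsonl", "flat"), vocab = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (!is.null(vocab) && length(vocab) == 1 && file.exists(vocab)) {
    vocab <- readLines(vocab)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fixed_vocab <- !is.null(vocab)
  seen <- if (fixed_vocab) as.character(vocab) else character()
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(seen)) assign(seen[i], i, envir = lookup)
  code_index <- function(code, lineno) {
    idx <- lookup[[code]]
    if (is.null(idx)) {
      if (fixed_vocab) stop("unknown code '", code, "' at line ", lineno,
                            " (fixed vocabulary)")
      seen[[length(seen) + 1L]] <<- code
      idx <- length(seen)
      assign(code, idx, envir = lookup)
    }
    idx
  }
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch({
      if (dialect == "jsonl") parse_jsonl_record(lines[[i]], code_index, i)
      else parse_flat_record(lines[[i]], code_index, i)
    }, error = function(e) stop("malformed record at line ", i, ": ",
                                conditionMessage(e), call. = FALSE))
    records[[i]] <- rec
  }
  ehr_corpus(seen, records)
}

parse_jsonl_record <- function(line, code_index, lineno) {
  obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (is.null(obj$pid) || is.null(obj$visits)) stop("missing pid or visits")
  visits <- lapply(obj$visits, function(v) {
    codes <- vapply(v$codes, function(cd) code_index(as.character(cd), lineno),
                    integer(1))
    ehr_visit(codes,
              time = v$t, loc = v$loc, label = v$label,
              duration = v$dur)
  })
  ehr_record(obj$pid, visits)
}

parse_flat_record <- function(line, code_index, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("expected pid<TAB>visits")
  visits <- lapply(strsplit(parts[2], ";", fixed = TRUE)[[1]], function(vs) {
    fields <- strsplit(vs, ",", fixed = TRUE)[[1]]
    if (length(fields) != 2) stop("expected label,codes in visit '", vs, "'")
    lab <- if (fields[1] == "-") NULL else as.integer(fields[1])
    codes_str <- strsplit(trimws(fields[2]), " +")[[1]]
    codes_str <- codes_str[nzchar(codes_str)]
    codes <- vapply(codes_str, function(cd) code_index(cd, lineno), integer(1),
                    USE.NAMES = FALSE)
    ehr_visit(codes, label = lab)
  })
  ehr_record(parts[1], visits)
}

#' Write a visit-sequence corpus
#'
#' Inverse of \code{\link{read_ehr_corpus}}: writes a file that reads back as
#' a field-for-field equal corpus (split tags are not serialized). Output is
#' deterministic: identical corpora produce byte-identical files.
#'
#' @param corpus an \code{\link{ehr_corpus}}.
#' @param path output file path.
#' @param dialect "jsonl" or "flat".
#' @export
write_ehr_corpus <- function(corpus, path, dialect = c("jsonl", "flat")) {
  dialect <- match.arg(dialect)
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  vocab <- corpus$vocab
  lines <- vapply(corpus$records, function(r) {
    if (dialect == "jsonl") {
      visits <- lapply(r$visits, function(v) {
        out <- list(codes = as.list(vocab[v$codes]))
        if (!is.null(v$time)) out$t <- v$time
        if (!is.null(v$loc)) out$loc <- v$loc
        if (!is.null(v$label)) out$label <- v$label
        if (!is.null(v$duration)) out$dur <- v$duration
        out
      })
      jsonlite::toJSON(list(pid = r$pid, visits = visits), auto_unbox = TRUE)
    } else {
      vs <- vapply(r$visits, function(v) {
        lab <- if (is.null(v$label)) "-" else as.character(v$label)
        paste0(lab, ",", paste(vocab[v$codes], collapse = " "))
      }, character(1))
      paste0(r$pid, "\t", paste(vs, collapse = ";"))
    }
  }, character(1))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Build 30-day readmission labels from timestamps and locations
#'
#' For every inpatient visit, the label is 1 exactly when another inpatient
#' visit starts within the window \code{(discharge, discharge + window_days]},
#' where \code{discharge = time + duration} (duration defaults to 0). A
#' readmission exactly \code{window_days} after release counts as positive.
#' Only inpatient visits are supervised (mask TRUE); other visits get mask
#' FALSE and no label.
#'
#' @param record an \code{\link{ehr_record}} whose visits all carry \code{time}
#'   and \code{loc}.
#' @param window_days readmission window in days (default 30).
#' @param inpatient location value identifying inpatient visits.
#' @return the record with labels and mask rebuilt.
#' @export
build_labels <- function(record, window_days = 30L, inpatient = "inpatient") {
  tms <- lapply(record$visits, function(v) v$time)
  locs <- lapply(record$visits, function(v) v$loc)
  if (any(vapply(tms, is.null, logical(1))) ||
      any(vapply(locs, is.null, logical(1)))) {
    stop("build_labels needs a time and location on every visit; ",
         "use a pre-labeled corpus otherwise")
  }
  tms <- unlist(tms)
  locs <- unlist(locs)
  inp <- locs == inpatient
  visits <- record$visits
  for (t in seq_along(visits)) {
    if (!inp[t]) {
      visits[[t]]$label <- NULL
      next
    }
    dur <- if (is.null(visits[[t]]$duration)) 0L else visits[[t]]$duration
    discharge <- tms[t] + dur
    readmit <- inp & tms > discharge & tms <= discharge + window_days
    readmit[t] <- FALSE
    visits[[t]]$label <- as.integer(any(readmit))
  }
  ehr_record(record$pid, visits, mask = inp)
}

#' Assign train/validation/test splits at the patient level
#'
#' @param corpus an \code{\link{ehr_corpus}}.
#' @param sizes integer vector \code{c(n_train, n_val, n_test)}; must sum to
#'   at most the number of records. Unassigned records get an NA tag.
#' @param seed RNG seed; the assignment is reproducible given the seed.
#' @return the corpus with its \code{split} field set.
#' @export
split_corpus <- function(corpus, sizes, seed = 1L) {
  n <- length(corpus$records)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3 || any(sizes < 0)) stop("sizes must be (n_train, n_val, n_test)")
  if (sum(sizes) > n) stop("requested split sizes exceed corpus size (",
                           sum(sizes), " > ", n, ")")
  ord <- with_seed(seed, sample.int(n))
  split <- rep(NA_character_, n)
  split[ord[seq_len(sizes[1])]] <- "train"
  if (sizes[2] > 0) split[ord[sizes[1] + seq_len(sizes[2])]] <- "validation"
  if (sizes[3] > 0) split[ord[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  corpus$split <- split
  corpus
}

#' Descriptive statistics of a corpus
#'
#' Event counts sum code occurrences over visits (within-visit duplicates are
#' already collapsed by set semantics).
#'
#' @param corpus an \code{\link{ehr_corpus}} with at least one record.
#' @return a list of class \code{ehr_corpus_stats} with fields
#'   \code{n_patients}, \code{n_visits}, \code{n_events},
#'   \code{avg_visits_per_patient}, \code{avg_events_per_patient},
#'   \code{n_unique_codes}.
#' @export
corpus_stats <- function(corpus) {
  n_p <- length(corpus$records)
  if (n_p == 0) stop("corpus is empty; statistics are undefined")
  n_v <- 0L
  n_e <- 0L
  used <- logical(length(corpus$vocab))
  for (r in corpus$records) {
    n_v <- n_v + length(r$visits)
    for (v in r$visits) {
      n_e <- n_e + length(v$codes)
      used[v$codes] <- TRUE
    }
  }
  structure(list(n_patients = n_p, n_visits = n_v, n_events = n_e,
                 avg_visits_per_patient = n_v / n_p,
                 avg_events_per_patient = n_e / n_p,
                 n_unique_codes = sum(used)),
            class = "ehr_corpus_stats")
}

#' @export
print.ehr_corpus_stats <- function(x, ...) {
  cat(sprintf(paste0("patients: %d\nvisits: %d\nevents: %d\n",
                     "avg visits/patient: %.2f\navg events/patient: %.2f\n",
                     "unique codes: %d\n"),
              x$n_patients, x$n_visits, x$n_events,
              x$avg_visits_per_patient, x$avg_events_per_patient,
              x$n_unique_codes))
  invisible(x)
}

#' Subset a corpus by split tag
#'
#' @param corpus a split-tagged corpus.
#' @param which one of "train", "validation", "test".
#' @return an \code{\link{ehr_corpus}} holding only the tagged records.
#' @export
corpus_subset <- function(corpus, which) {
  if (is.null(corpus$split)) stop("corpus has no split tags; run split_corpus first")
  keep <- !is.na(corpus$split) & corpus$split == which
  ehr_corpus(corpus$vocab, corpus$records[keep])
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based seed fan-out: one user-facing seed feeds independent
# component streams without one component shifting another's draws.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 1664525 + 1013904223) %% 2147483647)
}

# Stable hash of a vocabulary, used to guard checkpoint/corpus compatibility.
vocab_hash <- function(vocab) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(vocab), tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}
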