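#' Define a set of biogeographic areas
#'
#' Areas are identified by unique single-letter codes.  The default is the
#' five-area system used for tarantula biogeography: A = Indian
#' Subcontinent, B = Asia (non-Indian Indomalaya), C = East of the Wallace
#' Line, D = Americas, E = Africa.
#'
#' @param codes Character vector of unique single letters (2 to 16 areas).
#' @param names Optional long names, same length as `codes`; defaults to
#'   the codes themselves (or the five-area names when `codes` is left at
#'   its default).
#' @return An `area_set` object: a data frame with columns `code`, `name`.
#' @export
area_set <- function(codes = c("A", "B", "C", "D", "E"), names = NULL) {
  if (is.null(names)) {
    names <- if (identical(codes, c("A", "B", "C", "D", "E"))) {
      c("Indian Subcontinent", "Asia (non-Indian Indomalaya)",
        "East of the Wallace Line", "Americas", "Africa")
    } else codes
  }
  if (length(codes) < 2L || length(codes) > 16L)
    stop("between 2 and 16 areas are supported")
  if (any(nchar(codes) != 1L)) stop("area codes must be single characters")
  if (anyDuplicated(codes)) stop("area codes must be unique")
  if (length(names) != length(codes)) stop("'names' must match 'codes'")
  out <- data.frame(code = codes, name = names, stringsAsFactors = FALSE)
  class(out) <- c("area_set", "data.frame")
  out
}

# Canonical label of an area subset: letters sorted in area order.
normalize_state_label <- function(label, codes) {
  vapply(label, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- setdiff(ch, codes)
    if (length(bad))
      stop("unknown area code(s) '", paste(bad, collapse = ""),
           "' in range '", s, "'")
    if (anyDuplicated(ch)) stop("repeated area code in range '", s, "'")
    paste(codes[sort(match(ch, codes))], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Enumerate the allowed ancestral range states
#'
#' Builds the ordered state space of geographic ranges: all non-empty
#' subsets of the areas with cardinality at most `max_range_size`, minus an
#' explicit exclusion list, optionally preceded by the null (empty) range.
#' States are ordered by cardinality and then lexicographically, and the
#' null range, when present, is always state 1.  Exclusions remove exactly
#' the listed subsets (supersets must be listed explicitly), and excluded
#' states are absent from the space altogether rather than rate-zeroed.
#'
#' @param areas An [area_set()].
#' @param max_range_size Maximum number of areas in a range (default: all).
#' @param exclusions Character vector of excluded ranges as letter strings
#'   (e.g. `"BD"` for Asia + Americas); order and letter order irrelevant.
#' @param include_null Include the null range (needed by the DEC anagenetic
#'   process, where it is absorbing under extinction)?  Default `TRUE`.
#'   The null range always has zero probability at tips and at the root.
#' @return A `state_space` object: list with elements `areas`, `labels`
#'   (state labels, `""` for the null range), `size` (cardinalities),
#'   `max_range_size`, `exclusions`, `include_null`, `k` (number of
#'   states).
#' @export
build_state_space <- function(areas = area_set(),
                              max_range_size = nrow(areas),
                              exclusions = character(),
                              include_null = TRUE) {
  codes <- areas$code
  if (max_range_size < 1L || max_range_size > length(codes))
    stop("'max_range_size' must be between 1 and the number of areas")
  exclusions <- unique(normalize_state_label(exclusions, codes))
  labels <- character()
  for (m in seq_len(max_range_size)) {
    combs <- utils::combn(codes, m)
    labels <- c(labels, apply(combs, 2L, paste, collapse = ""))
  }
  labels <- setdiff(labels, exclusions)
  if (!length(labels)) stop("state space is empty after exclusions")
  if (include_null) labels <- c("", labels)
  out <- list(areas = areas, labels = labels, size = nchar(labels),
              max_range_size = as.integer(max_range_size),
              exclusions = exclusions, include_null = include_null,
              k = length(labels))
  class(out) <- "state_space"
  out
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", x$k, "states over", nrow(x$areas), "areas (",
      paste(x$areas$code, collapse = ""), "), max range size ",
      x$max_range_size, "\n", sep = "")
  if (length(x$exclusions))
    cat("  excluded:", paste(x$exclusions, collapse = ", "), "\n")
  if (x$include_null) cat("  null range included (state 1)\n")
  invisible(x)
}

#' Index of a range state in a state space
#'
#' @param space A [build_state_space()] object.
#' @param label Range label(s) as letter strings (letter order irrelevant);
#'   `""` is the null range.
#' @return Integer index (1-based) into `space$labels`.
#' @export
state_index <- function(space, label) {
  lab <- ifelse(label == "", "",
                normalize_state_label(label, space$areas$code))
  i <- match(lab, space$labels)
  if (anyNA(i)) {
    bad <- lab[is.na(i)]
    stop("range state(s) not in the allowed state space: ",
         paste(sQuote(bad), collapse = ", "))
  }
  i
}

# Non-null state indices (the support of tips and root prior).
nonnull_states <- function(space) {
  which(nzchar(space$labels))
}

#' Read an exclusion list
#'
#' One excluded area combination per line, as a letter string (e.g. `BD`);
#' blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the text file.
#' @return Character vector of excluded range labels.
#' @export
read_exclusions <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Load and validate taxon range codings
#'
#' Reads a two-column tab-separated file (taxon, area-letter string such as
#' `"AB"`; no header) and validates it against a state space and,
#' optionally, a chronogram: every tip must be coded, every observed state
#' must be in the allowed list.
#'
#' @param path Path to the TSV file.
#' @param space A [build_state_space()] object.
#' @param tree Optional chronogram; when given, a tip without a coding is
#'   an error, and a coding for an absent tip is an error under
#'   `strict = TRUE` and a dropped warning otherwise.
#' @param strict Logical, see above.  Default `TRUE`.
#' @return A named character vector of canonical range labels
#'   (taxon -> state), class `range_data`.
#' @export
load_range_codings <- function(path, space, tree = NULL, strict = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", col.names = c("taxon", "range"))
  if (anyDuplicated(tab$taxon))
    stop("duplicate coding for taxon: ",
         paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "))
  ranges <- vapply(seq_len(nrow(tab)), function(i) {
    lab <- tryCatch(normalize_state_label(tab$range[i], space$areas$code),
                    error = function(e) stop("taxon '", tab$taxon[i], "': ",
                                             conditionMessage(e)))
    lab
  }, character(1L))
  names(ranges) <- tab$taxon
  as_range_data(ranges, space, tree = tree, strict = strict)
}

#' Validate an in-memory range coding
#'
#' @param ranges Named character vector, taxon -> range letter string.
#' @inheritParams load_range_codings
#' @return A `range_data` named character vector of canonical labels.
#' @export
as_range_data <- function(ranges, space, tree = NULL, strict = TRUE) {
  lab <- normalize_state_label(unname(ranges), space$areas$code)
  names(lab) <- names(ranges)
  bad <- lab[!lab %in% space$labels | !nzchar(lab)]
  if (length(bad))
    stop("observed range(s) outside the allowed state space (excluded or ",
         "too large): ", paste(names(bad), "=", bad, collapse = ", "))
  if (!is.null(tree)) {
    uncoded <- setdiff(tree$tip.label, names(lab))
    if (length(uncoded))
      stop("tip(s) without a range coding: ",
           paste(uncoded, collapse = ", "))
    extra <- setdiff(names(lab), tree$tip.label)
    if (length(extra)) {
      if (strict)
        stop("coding(s) for absent tip(s): ", paste(extra, collapse = ", "))
      warning("dropping coding(s) for absent tip(s): ",
              paste(extra, collapse = ", "))
      lab <- lab[tree$tip.label]
    }
  }
  class(lab) <- "range_data"
  lab
}

#' Tally taxa per area
#'
#' @param ranges A `range_data` vector.
#' @param space The state space the ranges live in.
#' @return Named integer vector: number of taxa whose range includes each
#'   area.
#' @export
area_tally <- function(ranges, space) {
  codes <- space$areas$code
  vapply(codes, function(a) sum(grepl(a, unclass(ranges), fixed = TRUE)),
         integer(1L))
}

#' Default maximum range size from observed codings
#'
#' The largest observed tip-range cardinality, with a floor of 2.
#'
#' @param ranges A named character vector of range labels.
#' @return Integer.
#' @export
default_max_range_size <- function(ranges) {
  max(2L, max(nchar(unclass(ranges))))
}
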