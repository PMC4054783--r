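#' Construct a hexamer set
#'
#' A hexamer set is a named catalogue of unique 6-mers over the DNA alphabet
#' \{A,C,G,T\}, the unit of all concordance, density and selection analyses.
#' Motifs are uppercased on construction; duplicates are dropped with a
#' warning. Motifs are stored strand-naively: ESEs act on the pre-mRNA sense
#' sequence, so no reverse complementation happens anywhere downstream.
#'
#' @param motifs character vector of 6-mers (case-insensitive).
#' @param name label for the catalogue.
#' @return A character vector of unique uppercase hexamers with class
#'   `"hexamer_set"` and a `name` attribute.
#' @examples
#' hexamer_set(c("GAAGAA", "gaagac"), name = "demo")
#' @export
hexamer_set <- function(motifs, name = "set") {
  motifs <- toupper(as.character(motifs))
  if (length(motifs) == 0) {
    out <- character(0)
  } else {
    bad <- motifs[nchar(motifs) != 6L | grepl("[^ACGT]", motifs)]
    if (length(bad) > 0) {
      stop("invalid hexamer(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    if (anyDuplicated(motifs)) {
      warning(sprintf("%d duplicate motif(s) dropped from '%s'",
                      sum(duplicated(motifs)), name))
      motifs <- unique(motifs)
    }
    out <- motifs
  }
  structure(out, name = name, class = c("hexamer_set", "character"))
}

#' @export
print.hexamer_set <- function(x, ...) {
  cat(sprintf("<hexamer_set '%s': %d motifs>\n", set_name(x), length(x)))
  if (length(x) > 0) {
    cat(" ", paste(utils::head(unclass(x), 10), collapse = " "),
        if (length(x) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @rdname hexamer_set
#' @param x a `hexamer_set`.
#' @export
set_name <- function(x) {
  nm <- attr(x, "name")
  if (is.null(nm)) "set" else nm
}

#' Read / write plain-text motif lists
#'
#' One motif per line; `#` starts a comment; blank lines ignored;
#' case-insensitive on read, uppercase on write.
#'
#' @param path file path.
#' @param name catalogue label (defaults to the file base name).
#' @return `read_hexamer_set` returns a [hexamer_set()]; `write_hexamer_set`
#'   returns `path` invisibly.
#' @export
read_hexamer_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  hexamer_set(lines, name = name)
}

#' @rdname read_hexamer_set
#' @param set a `hexamer_set`.
#' @export
write_hexamer_set <- function(set, path) {
  writeLines(toupper(as.character(set)), path)
  invisible(path)
}

#' All 4,096 hexamers
#'
#' @return character vector of the full hexamer universe, in lexicographic
#'   order.
#' @export
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(do.call(paste0, g))
}

#' Derive hexamers from an octamer list
#'
#' Each octamer contributes its three constituent hexamers (offsets 1-6, 2-7,
#' 3-8); occurrence counts are tallied across the whole list (a hexamer
#' occurring at several offsets within one octamer counts once per offset)
#' and hexamers reaching `min_occurrences` are returned. This is the rule by
#' which the published pseudoexon-based catalogue reduced its 2,069 octamers
#' to 238 hexamers (minimum of seven occurrences).
#'
#' @param octamers character vector of 8-mers over ACGT; duplicates allowed
#'   and counted.
#' @param min_occurrences minimum total occurrence count to retain a hexamer.
#' @param name label for the derived set.
#' @return A [hexamer_set()].
#' @examples
#' hexamers_from_octamers(rep("AAAAAAAA", 3)) # 9 occurrences of AAAAAA
#' @export
hexamers_from_octamers <- function(octamers, min_occurrences = 7,
                                   name = "octamer-derived") {
  octamers <- toupper(as.character(octamers))
  if (length(octamers) == 0) return(hexamer_set(character(0), name = name))
  bad <- octamers[nchar(octamers) != 8L | grepl("[^ACGT]", octamers)]
  if (length(bad) > 0) {
    stop("invalid octamer(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  hexes <- c(substr(octamers, 1, 6), substr(octamers, 2, 7),
             substr(octamers, 3, 8))
  counts <- table(hexes)
  keep <- names(counts)[counts >= min_occurrences]
  hexamer_set(sort(keep), name = name)
}

#' Motifs present in at least k catalogues
#'
#' `k = length(sets)` gives the full intersection, `k = 1` the union. This is
#' how consensus intersect catalogues (e.g. the "at least two" / "at least
#' three" sets) are built from the raw ESE screens.
#'
#' @param sets a list of [hexamer_set()] objects (or character vectors).
#' @param k minimum number of catalogues a motif must appear in.
#' @param name label for the result.
#' @return A [hexamer_set()] of motifs found in `>= k` of the inputs.
#' @export
intersect_at_least <- function(sets, k, name = sprintf("int%d", k)) {
  if (length(sets) == 0) stop("'sets' must contain at least one hexamer set")
  if (k < 1 || k > length(sets)) {
    stop("'k' must be between 1 and the number of sets")
  }
  counts <- table(unlist(lapply(sets, function(s) unique(toupper(s)))))
  hexamer_set(sort(names(counts)[counts >= k]), name = name)
}

#' Union size by inclusion-exclusion
#'
#' Size of the union of two sets given their sizes and the size of their
#' intersection: `n1 + n2 - n_common`. Used e.g. to combine counts of motifs
#' reported at 5' and 3' exon ends into one catalogue size.
#'
#' @param n1,n2 set sizes.
#' @param n_common size of the intersection; must not exceed either size.
#' @return integer union size.
#' @examples
#' union_size(103, 198, 63) # 238
#' @export
union_size <- function(n1, n2, n_common) {
  stopifnot(n1 >= 0, n2 >= 0, n_common >= 0)
  if (n_common > min(n1, n2)) {
    stop("'n_common' cannot exceed the size of either set")
  }
  as.integer(n1 + n2 - n_common)
}

#' Base composition of a hexamer set
#'
#' Fractions of A, C, G, T over all `6 * length(set)` base slots, plus the
#' purine (AG) and GC fractions. Descriptive only; optionally a chi-square
#' goodness-of-fit against a user-supplied background composition.
#'
#' @param set a [hexamer_set()]; must be non-empty.
#' @param background optional numeric vector of background fractions named
#'   A, C, G, T; if given, a chi-square test of the observed base counts
#'   against it is attached.
#' @return A list with `fractions` (named A, C, G, T), `AG`, `GC`, `n_bases`,
#'   and optionally `chisq_p`.
#' @export
base_composition <- function(set, background = NULL) {
  if (length(set) == 0) stop("composition of an empty set is undefined")
  chars <- strsplit(paste(as.character(set), collapse = ""), "")[[1]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  frac <- counts / sum(counts)
  out <- list(fractions = frac,
              AG = unname(frac["A"] + frac["G"]),
              GC = unname(frac["G"] + frac["C"]),
              n_bases = sum(counts))
  if (!is.null(background)) {
    bg <- background[c("A", "C", "G", "T")]
    stopifnot(!anyNA(bg))
    out$chisq_p <- stats::chisq.test(counts, p = bg / sum(bg))$p.value
  }
  out
}

#' Per-position information content
#'
#' For each of the six motif positions the information content in bits,
#' `2 + sum_b f_b * log2(f_b)` over bases with nonzero frequency; 2 bits for
#' a perfectly conserved position, 0 for uniform base usage.
#'
#' @param set a non-empty [hexamer_set()].
#' @return numeric vector of six values in `[0, 2]`.
#' @export
positional_information <- function(set) {
  if (length(set) == 0) stop("information content of an empty set is undefined")
  m <- matrix(unlist(strsplit(as.character(set), "")), ncol = 6, byrow = TRUE)
  vapply(seq_len(6), function(j) {
    f <- tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), 4)
    f <- f / sum(f)
    f <- f[f > 0]
    2 + sum(f * log2(f))
  }, numeric(1))
}
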