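#' Normalize chromosome names
#'
#' Strips an optional leading \code{"chr"} (any case), maps \code{"MT"} to
#' \code{"M"}, and upper-cases the sex chromosomes, so that \code{"chr3"},
#' \code{"Chr3"} and \code{"3"} all become \code{"3"}. The mapping is
#' idempotent; one canonical spelling (no prefix) is used internally and a
#' \code{"chr"} prefix is re-added when writing UCSC-style files.
#'
#' @param x character vector of chromosome names.
#' @return character vector of canonical names.
#' @examples
#' normalizeChrom(c("chr3", "3", "chrX", "MT", "chrM"))
#' @export
normalizeChrom <- function(x) {
    x <- as.character(x)
    x <- sub("^[Cc][Hh][Rr]", "", x)
    x <- toupper(x)
    x[x == "MT"] <- "M"
    x
}

## chromosomes eligible for arm-level calls ("M" never is)
.ARM_CHROMS <- c(as.character(1:22), "X", "Y")

.DIRECTIONS <- c("loss", "gain")

## An arm event is the string "<chrom><p|q>_<loss|gain>", e.g. "3q_loss".
.EVENT_RE <- "^(1[0-9]|2[0-2]|[1-9]|X|Y)(p|q)_(loss|gain)$"

makeEvent <- function(arm, direction) {
    ev <- paste0(arm, "_", direction)
    bad <- !grepl(.EVENT_RE, ev)
    if (any(bad))
        stop("invalid arm event(s): ", paste(unique(ev[bad]), collapse = ", "))
    ev
}

eventArm <- function(events) sub("_(loss|gain)$", "", events)

eventDirection <- function(events) sub("^.*_", "", events)

## canonical form of an event set: sorted unique labels
normalizeEventSet <- function(events) {
    events <- unique(as.character(events))
    bad <- !grepl(.EVENT_RE, events)
    if (any(bad))
        stop("invalid arm event(s): ", paste(events[bad], collapse = ", "))
    sort(events)
}

eventSetId <- function(events) {
    if (length(events) == 0L) "root" else paste(normalizeEventSet(events),
                                                collapse = "+")
}

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's RNG afterwards.  All stochastic simulator output flows through
## this, so identical seeds give identical files.
withSeed <- function(seed, code) {
    if (!is.null(get0(".Random.seed", envir = globalenv()))) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

## fixed-width numeric formatting used for byte-deterministic SVG output
fmtNum <- function(x) sprintf("%.9f", x)

## Largest-remainder apportionment of n into parts proportional to `frac`
## (fractions need not sum to 1; counts sum to round(n * sum(frac)) scaled
## exactly so that frac_i * n integral values are hit exactly).
largestRemainder <- function(frac, n) {
    ideal <- frac * n
    base <- floor(ideal + 1e-9)
    rem <- ideal - base
    extra <- round(sum(ideal)) - sum(base)
    counts <- base
    if (extra > 0) {
        ord <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                     method = "radix")
        counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
    }
    as.integer(counts)
}
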