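#' Correct driver-mutation VAFs for normal contamination
#'
#' Bulk variant allele frequencies are depressed by admixed normal cells.
#' Because the G-alpha mutations (GNAQ/GNA11) are truncal and heterozygous
#' in this tumor type, their true VAF is 50%; every VAF is therefore
#' rescaled by \code{0.5 / raw_vaf(anchor)}, which sets the anchor's
#' corrected VAF to exactly 50% and corrects the remaining genes by the
#' same purity factor. Values that rescale above 1 are clamped with a
#' warning.
#'
#' @param records mutation record data.frame (see [readMutationTable()]).
#' @param anchorGene symbol of the anchor gene, typically \code{"GNAQ"} or
#'   \code{"GNA11"}; must be present with raw VAF > 0.
#' @return the records with \code{corrected_vaf} filled in.
#' @examples
#' rec <- data.frame(gene = c("GNAQ", "BAP1"), raw_vaf = c(0.31, 0.20))
#' correctVAFs(rec, "GNAQ")$corrected_vaf   # 0.5 and 0.3226
#' @export
correctVAFs <- function(records, anchorGene) {
    idx <- which(records$gene == anchorGene)
    if (length(idx) == 0L)
        stop("anchor gene ", anchorGene, " absent from mutation table")
    anchorRaw <- records$raw_vaf[idx[1L]]
    if (anchorRaw <= 0)
        stop("anchor gene ", anchorGene, " has raw VAF of 0")
    corrected <- records$raw_vaf * 0.5 / anchorRaw
    if (any(corrected > 1)) {
        warning("corrected VAF above 1 for: ",
                paste(records$gene[corrected > 1], collapse = ", "),
                "; clamped to 1")
        corrected <- pmin(corrected, 1)
    }
    corrected[idx] <- 0.5
    records$corrected_vaf <- corrected
    records
}

#' Attribute driver mutations to clone-tree branches
#'
#' Under a heterozygous diploid assumption a mutation's expected clone
#' percentage is \code{min(100, 200 * corrected_vaf)}. Each mutation is
#' attached to the non-root node whose inclusive percentage is nearest to
#' the expected percentage, provided that distance is within
#' \code{tolerance} percentage points and the nearest node is unique;
#' otherwise the mutation is starred and listed at the root (it occurs in
#' a subclone that cannot be matched to a specific branch). Truncal
#' mutations (expected percentage within tolerance of 100) that find no
#' unique match attach to the trunk when the root has exactly one child.
#'
#' For the recurrent uveal-melanoma drivers with known arm locations
#' (BAP1 3p, SF3B1 2q, EIF1AX Xp, GNAQ 9q, GNA11 19p) a caveat is logged
#' when an assigned mutation lies on an arm lost in its clone: the
#' heterozygous-diploid conversion is then only approximate.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param records mutation records with \code{corrected_vaf} set (see
#'   [correctVAFs()]).
#' @param tolerance match tolerance in percentage points.
#' @return the tree with its \code{mutations} slot filled
#'   (\code{expected_pct}, \code{node}, \code{starred}).
#' @export
assignMutations <- function(tree, records, tolerance = 5.0) {
    if (anyNA(records$corrected_vaf) && nrow(records) > 0L)
        stop("corrected_vaf unset; run correctVAFs() first")
    nd <- tree@nodes
    nonRoot <- which(!is.na(nd$parent))
    pct <- nd$inclusivePercentage[nonRoot]
    ids <- nd$id[nonRoot]
    records$expected_pct <- pmin(100, 200 * records$corrected_vaf)
    records$node <- NA_character_
    records$starred <- FALSE
    rootKids <- childIds(tree, rootId(tree))
    for (i in seq_len(nrow(records))) {
        exp <- records$expected_pct[i]
        assigned <- NA_character_
        if (length(pct)) {
            d <- abs(pct - exp)
            dmin <- min(d)
            nearest <- which(d <= dmin + 1e-9)
            if (dmin <= tolerance && length(nearest) == 1L)
                assigned <- ids[nearest]
        }
        if (is.na(assigned) && exp >= 100 - tolerance &&
            length(rootKids) == 1L)
            assigned <- rootKids
        if (is.na(assigned)) {
            records$starred[i] <- TRUE
        } else {
            records$node[i] <- assigned
        }
    }
    ## copy-number caveat for drivers with known arm locations
    driverArm <- c(BAP1 = "3p", SF3B1 = "2q", EIF1AX = "Xp",
                   GNAQ = "9q", GNA11 = "19p")
    for (i in which(!is.na(records$node))) {
        arm <- driverArm[records$gene[i]]
        if (is.na(arm)) next
        cum <- nd$cumulativeEvents[[match(records$node[i], nd$id)]]
        if (makeEvent(arm, "loss") %in% cum)
            message("caveat: ", records$gene[i], " lies on lost arm ", arm,
                    " in its assigned clone; the diploid VAF-to-percentage ",
                    "conversion is approximate")
    }
    tree@mutations <- records
    methods::validObject(tree)
    tree
}
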