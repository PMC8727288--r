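#' Reconcile VCF alleles with a weight-panel allele pair
#'
#' Determines how a genotype file's REF/ALT pair maps onto the panel's
#' (risk, other) pair, allowing for the file being on the opposite strand.
#' `"direct"` means the pair order matches -- REF is the risk allele, so the
#' risk dosage is `2 - ALT dosage`; `"flipped"` means the order is reversed
#' -- ALT is the risk allele and the risk dosage equals the ALT dosage. The
#' `strand_flip_*` variants mean the same after reverse-complementing the
#' file's alleles. Strand-ambiguous (palindromic A/T and C/G) pairs cannot
#' be oriented by allele identity; under the default policy they are
#' excluded (flagged `"ambiguous"`), under `policy = "trust_file"` the
#' file's strand is accepted at face value.
#'
#' @param vcfRef,vcfAlt file REF and ALT alleles (single bases).
#' @param panelRisk,panelOther panel risk and other alleles.
#' @param policy `"exclude_ambiguous"` (default) or `"trust_file"`.
#' @return one of `"direct"`, `"flipped"`, `"strand_flip_direct"`,
#'   `"strand_flip_flipped"`, `"ambiguous"`, `"irreconcilable"`.
#' @examples
#' harmonizeAlleles("A", "G", "G", "A")  # "flipped": ALT carries the risk
#' harmonizeAlleles("A", "G", "C", "T")  # "strand_flip_flipped"
#' @export
harmonizeAlleles <- function(vcfRef, vcfAlt, panelRisk, panelOther,
                             policy = c("exclude_ambiguous", "trust_file")) {
    policy <- match.arg(policy)
    al <- c(vcfRef, vcfAlt, panelRisk, panelOther)
    if (!all(al %in% .BASES))
        stop("alleles must be single bases A/C/G/T")
    palindromic <- .COMP[[vcfRef]] == vcfAlt
    if (palindromic && policy == "exclude_ambiguous") return("ambiguous")
    if (vcfRef == panelRisk && vcfAlt == panelOther) return("direct")
    if (vcfAlt == panelRisk && vcfRef == panelOther) return("flipped")
    if (palindromic) return("irreconcilable")  # trust_file already matched or failed
    rcRef <- .COMP[[vcfRef]]; rcAlt <- .COMP[[vcfAlt]]
    if (rcRef == panelRisk && rcAlt == panelOther) return("strand_flip_direct")
    if (rcAlt == panelRisk && rcRef == panelOther) return("strand_flip_flipped")
    "irreconcilable"
}

#' Apply an orientation to an ALT-allele dosage
#'
#' @param altDosage dosage of the file's ALT allele (0/1/2 or NA).
#' @param orientation a [harmonizeAlleles()] result.
#' @return risk-allele dosage; `NA` for ambiguous/irreconcilable orientations.
#' @export
orientDosage <- function(altDosage, orientation) {
    switch(orientation,
           flipped = , strand_flip_flipped = altDosage,
           direct = , strand_flip_direct = 2 - altDosage,
           NA * altDosage)
}
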