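#' Write genotypes as an unphased diploid VCF
#'
#' Emits REF = other allele, ALT = risk allele (so ALT dosage equals the
#' risk-allele dosage), GT-only FORMAT, missing genotypes as `./.`.
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(genotypes, path) {
    pan <- snpPanel(genotypes)
    d <- dosageMatrix(genotypes)
    gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtCode[as.character(d[ok])]
    hdr <- c("##fileformat=VCFv4.2",
             "##source=cllprs",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- cbind(pan$chrom, pan$pos, pan$variant_id, pan$other_allele,
                  pan$risk_allele, ".", ".", ".", "GT", gt)
    writeLines(c(hdr, apply(body, 1L, paste, collapse = "\t")), path)
    invisible(path)
}

.gtToAltDosage <- function(gt) {
    gt <- sub(":.*", "", gt)
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
}

#' Read panel variants from a VCF into risk-allele dosages
#'
#' Parses GT fields, matches records to the weight panel (by variant id when
#' the VCF ID column is informative, otherwise by chrom:pos), orients each
#' record's alleles against the panel via [harmonizeAlleles()] (allowing
#' strand flips), and converts to risk-allele dosage. Records not in the
#' panel are ignored with a message; panel variants whose alleles cannot be
#' reconciled (including strand-ambiguous pairs under the default policy)
#' are excluded and reported in the returned object's metadata.
#'
#' @param path VCF file (v4.x, GT field).
#' @param panel SNP weight panel.
#' @param samples optional sample table to attach (matched by `sample_id`).
#' @param policy harmonization policy, see [harmonizeAlleles()].
#' @return \linkS4class{GenotypeExperiment}; excluded variants recorded in
#'   `metadata(x)$excluded_variants`.
#' @export
readGenotypesVCF <- function(path, panel, samples = NULL,
                             policy = "exclude_ambiguous") {
    panel <- S4Vectors::DataFrame(panel)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    key <- ifelse(!is.na(fix$ID) & fix$ID != ".", fix$ID,
                  paste0(fix$CHROM, ":", fix$POS))
    panKey <- panel$variant_id
    hit <- match(panKey, key)
    posKey <- paste0(panel$chrom, ":", panel$pos)
    hit[is.na(hit)] <- match(posKey[is.na(hit)], key)
    nIgnored <- nrow(fix) - sum(!is.na(hit))
    if (nIgnored > 0)
        message(nIgnored, " VCF record(s) not in the panel; ignored")
    if (all(is.na(hit)))
        stop("no VCF records overlap the panel")
    excluded <- data.frame(variant_id = character(), reason = character())
    d <- matrix(NA_real_, nrow(panel), ncol(gt),
                dimnames = list(panel$variant_id, colnames(gt)))
    for (i in which(!is.na(hit))) {
        j <- hit[i]
        orient <- harmonizeAlleles(fix$REF[j], fix$ALT[j],
                                   panel$risk_allele[i],
                                   panel$other_allele[i], policy = policy)
        if (orient %in% c("ambiguous", "irreconcilable")) {
            excluded <- rbind(excluded,
                              data.frame(variant_id = panel$variant_id[i],
                                         reason = orient))
            next
        }
        d[i, ] <- orientDosage(.gtToAltDosage(gt[j, ]), orient)
    }
    keep <- setdiff(seq_len(nrow(panel)),
                    c(which(is.na(hit)),
                      match(excluded$variant_id, panel$variant_id)))
    if (!length(keep)) stop("no panel variants usable after harmonization")
    sampDF <- S4Vectors::DataFrame(sample_id = colnames(gt))
    if (!is.null(samples)) {
        samples <- S4Vectors::DataFrame(samples)
        m <- match(colnames(gt), samples$sample_id)
        if (any(is.na(m))) stop("sample table lacks some VCF samples")
        sampDF <- samples[m, ]
    }
    out <- GenotypeExperiment(d[keep, , drop = FALSE],
                              panel[keep, ], sampDF)
    S4Vectors::metadata(out)$excluded_variants <- excluded
    out
}

#' Write / read a dosage TSV (samples x variants, NA for missing)
#'
#' @param genotypes \linkS4class{GenotypeExperiment}.
#' @param path file path.
#' @return `path` / \linkS4class{GenotypeExperiment}.
#' @export
writeDosageTSV <- function(genotypes, path) {
    d <- t(dosageMatrix(genotypes))
    df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDosageTSV
#' @param panel SNP panel whose variants select and order the columns.
#' @param samples optional sample table to attach.
#' @export
readDosageTSV <- function(path, panel, samples = NULL) {
    panel <- S4Vectors::DataFrame(panel)
    df <- read.delim(path, check.names = FALSE)
    found <- intersect(panel$variant_id, colnames(df))
    if (!length(found)) stop("no panel variants in dosage table")
    d <- t(as.matrix(df[, found, drop = FALSE]))
    colnames(d) <- df$sample_id
    sampDF <- S4Vectors::DataFrame(sample_id = df$sample_id)
    if (!is.null(samples)) {
        samples <- S4Vectors::DataFrame(samples)
        m <- match(df$sample_id, samples$sample_id)
        if (any(is.na(m))) stop("sample table lacks some dosage-table samples")
        sampDF <- samples[m, ]
    }
    GenotypeExperiment(d, panel[match(found, panel$variant_id), ], sampDF)
}

#' Write / read the SNP weight panel as TSV
#'
#' Columns: variant_id, chrom, pos, risk_allele, other_allele, weight_log_or,
#' freq_<ancestry>...
#'
#' @param panel panel `DataFrame`.
#' @param path file path.
#' @export
writePanelTSV <- function(panel, path) {
    df <- as.data.frame(panel)
    names(df)[names(df) == "weight"] <- "weight_log_or"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePanelTSV
#' @export
readPanelTSV <- function(path) {
    df <- read.delim(path)
    names(df)[names(df) == "weight_log_or"] <- "weight"
    df$chrom <- as.character(df$chrom)
    S4Vectors::DataFrame(df)
}

#' Write / read the per-sample table as TSV
#'
#' @param samples sample `DataFrame`/`data.frame`.
#' @param path file path.
#' @export
writeSamplesTSV <- function(samples, path) {
    write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeSamplesTSV
#' @export
readSamplesTSV <- function(path) {
    S4Vectors::DataFrame(read.delim(path))
}
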