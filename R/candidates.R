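# Candidate SNV sites: construction, VCF import, mutation-class filtering.

#' Construct a candidate SNV site
#'
#' A candidate site is one locus flagged by a variant caller and awaiting
#' refinement. Only biallelic SNVs are supported: both alleles must be
#' canonical bases and differ.
#'
#' @param chrom reference sequence name
#' @param pos 1-based position (VCF convention)
#' @param ref_base,alt_base single characters among A/C/G/T, distinct
#' @param mutation_class optional functional annotation (e.g. "exonic")
#' @param vaf optional variant allele frequency in \[0, 1\]
#' @param label optional ground-truth label, "mutation" or "artefact"
#' @return an object of class `candidate_site`
#' @export
candidate_site <- function(chrom, pos, ref_base, alt_base,
                           mutation_class = NA_character_, vaf = NA_real_,
                           label = NA_character_) {
  if (!is_scalar_int(pos) || pos < 1) stop_data("pos must be an integer >= 1")
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  if (!ref_base %in% BASES || !alt_base %in% BASES)
    stop_data("ref/alt must be canonical bases (SNVs only), got ",
              ref_base, ">", alt_base)
  if (ref_base == alt_base) stop_data("ref_base and alt_base must differ")
  if (!is.na(vaf) && (vaf < 0 || vaf > 1)) stop_data("vaf must lie in [0, 1]")
  if (!is.na(label) && !label %in% c("mutation", "artefact"))
    stop_data("label must be 'mutation' or 'artefact'")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref_base = ref_base, alt_base = alt_base,
                 mutation_class = mutation_class, vaf = vaf, label = label),
            class = "candidate_site")
}

#' @export
print.candidate_site <- function(x, ...) {
  cat(sprintf("<candidate_site> %s:%d %s>%s class=%s vaf=%s label=%s\n",
              x$chrom, x$pos, x$ref_base, x$alt_base,
              x$mutation_class, format(x$vaf), x$label))
  invisible(x)
}

#' Default mutation-class whitelist
#'
#' Functional categories (ANNOVAR `Func.refGene` vocabulary) retained by
#' default when filtering candidate lists.
#'
#' @return character vector of 9 class names
#' @export
default_mutation_classes <- function() {
  c("exonic", "ncRNA_exonic", "splicing", "UTR3", "UTR5", "UTR5;UTR3",
    "downstream", "upstream", "upstream;downstream")
}

#' Filter candidates by functional mutation class
#'
#' Order-preserving subset of `sites` whose `mutation_class` belongs to
#' `allowed_classes`. An empty `allowed_classes` disables filtering and
#' returns the input unchanged. When filtering is enabled, candidates with
#' missing annotation are removed.
#'
#' @param sites list of [candidate_site()] objects
#' @param allowed_classes character vector of retained classes;
#'   defaults to [default_mutation_classes()]
#' @return filtered list of candidate sites
#' @export
filter_candidates <- function(sites, allowed_classes = default_mutation_classes()) {
  if (length(allowed_classes) == 0) return(sites)
  keep <- vapply(sites, function(s) {
    !is.na(s$mutation_class) && s$mutation_class %in% allowed_classes
  }, logical(1))
  sites[keep]
}

#' Read candidate SNVs from a VCF file
#'
#' Parses a VCF 4.x file and returns the biallelic SNV records as candidate
#' sites. The functional class is read from an INFO key; training labels can
#' come from a second INFO key or from a sidecar TSV with columns
#' chrom, pos, ref, alt, label.
#'
#' @param path VCF file (plain or bgzipped)
#' @param class_key INFO key holding the functional class
#' @param vaf_key optional INFO key holding the variant allele frequency
#' @param label_key optional INFO key holding a mutation/artefact label
#' @param labels_tsv optional path to a label sidecar TSV
#' @return list of [candidate_site()] objects; non-SNV records are dropped
#'   with a message
#' @export
read_candidates <- function(path, class_key = "Func.refGene",
                            vaf_key = NULL, label_key = NULL,
                            labels_tsv = NULL) {
  if (!file.exists(path)) stop_usage("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx)))  # a single record comes back as a bare vector
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(list())
  snv <- fix$REF %in% BASES & fix$ALT %in% BASES & fix$REF != fix$ALT
  snv[is.na(snv)] <- FALSE
  if (any(!snv))
    message(sum(!snv), " non-SNV or malformed record(s) skipped")
  classes <- tryCatch(vcfR::extract.info(vcf, element = class_key),
                      error = function(e) rep(NA_character_, nrow(fix)))
  vafs <- if (!is.null(vaf_key)) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = vaf_key)))
  } else rep(NA_real_, nrow(fix))
  labels <- if (!is.null(label_key)) {
    vcfR::extract.info(vcf, element = label_key)
  } else rep(NA_character_, nrow(fix))

  if (!is.null(labels_tsv)) {
    tab <- read.delim(labels_tsv, stringsAsFactors = FALSE)
    key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt)
    want <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT)
    labels <- tab$label[match(want, key)]
  }

  idx <- which(snv)
  lapply(idx, function(i) {
    candidate_site(fix$CHROM[i], as.integer(fix$POS[i]), fix$REF[i],
                   fix$ALT[i],
                   mutation_class = classes[i] %||% NA_character_,
                   vaf = vafs[i],
                   label = if (is.na(labels[i])) NA_character_ else labels[i])
  })
}
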