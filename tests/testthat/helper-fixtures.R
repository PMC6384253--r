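# Fixtures are built in code; brute-force oracles below re-evaluate filter
# predicates independently of the package's vectorized implementations.

# PED text for the 22-member three-generation family fixture
family_ped_lines <- function() {
  ped <- pedigree_template()
  sex <- ifelse(ped$sex == "male", "1", "2")
  aff <- ifelse(ped$affected == "affected", "2", "1")
  paste("FAM1", ped$id,
        ifelse(is.na(ped$father_id), "0", ped$father_id),
        ifelse(is.na(ped$mother_id), "0", ped$mother_id),
        sex, aff)
}

trio_ped_lines <- function() {
  c("T1 DAD 0 0 1 1",
    "T1 MOM 0 0 2 1",
    "T1 KID DAD MOM 1 2")
}

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="mq">',
    '##INFO=<ID=MQ0,Number=1,Type=Integer,Description="mq0">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="dp">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="fs">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="gene">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="region">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="csq">',
    '##INFO=<ID=AF_1000G,Number=1,Type=Float,Description="af">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "1000", "rs100", "A", "G", "250", ".",
            "MQ=55;MQ0=0;DP=60;FS=1.2;GENE=G1;REGION=exonic;CSQCLASS=nonsynonymous;AF_1000G=0.01",
            "GT:DP:AD", "0/1:40:20,20", "0/0:50:50,0", "1/1:44:1,43"),
          collapse = "\t"),
    paste(c("chr2", "2000", ".", "C", "T", "90", ".",
            "MQ=48;MQ0=1;DP=55;FS=0.5;GENE=G2;REGION=intronic;CSQCLASS=noncoding",
            "GT:DP:AD", "0/0:30:30,0", "0/1:36:20,16", "./.:.:."),
          collapse = "\t"),
    paste(c("chr3", "3000", "rs300", "G", "A,T", "120", ".",
            "MQ=50;MQ0=0;DP=70;FS=2;GENE=G3;REGION=exonic;CSQCLASS=synonymous;AF_1000G=0.2",
            "GT:DP:AD", "1/2:60:10,25,25", "0/1:62:40,22,0", "0/0:58:58,0,0"),
          collapse = "\t"))
}

read_ped_fixture <- function(lines) read_ped(lines)

# ---- brute-force oracles (plain loops over rows and calls) ----

brute_qc_keep <- function(variants, th = list(mq = 30, mq0 = 4, dp = 5,
                                              qual = 50, fs = 10)) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vals <- c(v$mq, v$mq0, v$dp, v$qual, v$fs)
    if (anyNA(vals)) { keep[i] <- FALSE; next }
    keep[i] <- v$mq >= th$mq && v$mq0 <= th$mq0 && v$dp >= th$dp &&
      v$qual >= th$qual && v$fs <= th$fs
  }
  keep
}

brute_functional_keep <- function(variants, max_af = 0.05, min_depth = 6,
                                  min_vaf = 0.3) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (identical(v$csq_class, "synonymous")) next
    freqs <- unlist(v[af_cols])
    freqs <- freqs[!is.na(freqs)]
    if (length(freqs) > 0 && max(freqs) > max_af) next
    calls <- v$calls[[1]]
    carriers <- calls[!is.na(calls$carrier) & calls$carrier, ]
    if (nrow(carriers) == 0) next
    if (mean(carriers$depth, na.rm = TRUE) < min_depth) next
    if (mean(carriers$alt_reads / carriers$depth, na.rm = TRUE) < min_vaf) next
    keep[i] <- TRUE
  }
  keep
}

brute_segregation_keep <- function(variants, required, excluded) {
  shared <- logical(nrow(variants))
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    calls <- variants$calls[[i]]
    carrier_of <- function(id) {
      cc <- calls$carrier[calls$sample_id == id]
      if (length(cc) == 0) NA else cc
    }
    ok <- TRUE
    for (id in required) {
      cc <- carrier_of(id)
      if (is.na(cc) || !cc) { ok <- FALSE; break }
    }
    shared[i] <- ok
    if (!ok) next
    bad <- FALSE
    for (id in excluded) {
      cc <- carrier_of(id)
      if (!is.na(cc) && cc) { bad <- TRUE; break }
    }
    keep[i] <- !bad
  }
  list(shared = shared, keep = keep)
}

# conservation check for every report attached to a cascade result
expect_reports_conserve <- function(reports) {
  for (r in reports) {
    expect_identical(r$output + sum(r$reasons), r$input)
  }
}
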