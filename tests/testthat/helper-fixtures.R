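# Small builders shared across tests. All fixtures are generated in code.

make_gm <- function(dosage, pos = NULL, chrom = NULL, populations = NULL,
                    ref = NULL, alt = NULL, ...) {
  s <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(s) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", s)
  if (is.null(ref)) ref <- rep("A", s)
  if (is.null(alt)) alt <- rep("G", s)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  genotype_matrix(dosage, chrom = chrom, pos = pos, ref = ref, alt = alt,
                  populations = populations, ...)
}

two_pop_map <- function(n_x, n_y, prefix_x = "X", prefix_y = "Y") {
  stats::setNames(c(rep("popX", n_x), rep("popY", n_y)),
                  c(paste0(prefix_x, seq_len(n_x)),
                    paste0(prefix_y, seq_len(n_y))))
}

# A five-record, three-sample VCF exercising missing genotypes, half calls,
# phasing, invariant ALT=".", INFO fields and DP.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "chr1\t100\t.\tA\tG\t90\tPASS\tQD=25;MQ=58\tGT:DP\t0/0:12\t0/1:9\t1/1:20",
    "chr1\t200\t.\tC\tT\t80\tPASS\tQD=1.5;MQ=60\tGT:DP\t./.:3\t0/0:8\t0/1:7",
    "chr1\t300\t.\tG\t.\t50\tPASS\tMQ=44\tGT:DP\t0/0:10\t0/0:11\t0/0:9",
    "chr1\t400\t.\tT\tA\t95\tPASS\tQD=30;MQ=59\tGT:DP\t0|1:15\t1|1:14\t0|0:13",
    "chr1\t500\t.\tA\tC,T\t60\tPASS\tQD=12;MQ=55\tGT:DP\t0/0:9\t0/2:10\t./1:8"),
    path)
  path
}

# Region fixture: one gene (100-200) with CDS 100-140 and 180-200.
write_fixture_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t200\t.\t+\t.\tID=geneA;Name=geneA",
    "chr1\ttest\tCDS\t100\t140\t.\t+\t0\tID=cdsA1;Parent=geneA",
    "chr1\ttest\tCDS\t180\t200\t.\t+\t0\tID=cdsA2;Parent=geneA"),
    path)
  path
}

# Copy one focal haplotype across every haplotype of a population inside a
# region: a planted, fully fixed extended haplotype (hard-sweep surrogate).
plant_fixed_haplotype <- function(gm, population, chrom, start, end) {
  idx <- which(gm$chrom == chrom & gm$pos >= start & gm$pos <= end)
  rows <- match(population_samples(gm, population), gm$samples)
  src <- gm$hap1[rows[1], idx]
  for (r in rows) {
    gm$hap1[r, idx] <- src
    gm$hap2[r, idx] <- src
  }
  gm$dosage[rows, idx] <- 2L * matrix(src, length(rows), length(idx),
                                      byrow = TRUE)
  gm
}
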