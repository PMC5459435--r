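#' Write a simulated study as a fixture bundle
#'
#' Serializes a toy genome, its planted-signal truth table and the two
#' read libraries as the plain-text formats the pipeline consumes:
#' `chrom.sizes` (TSV), `genes.gff3` (GFF3, 1-based closed),
#' `cgis.bed`/`repeats.bed`/`cpg.bed` (BED, 0-based half-open; the repeat
#' name column carries the class), `reads_control.bed`/`reads_exposed.bed`
#' (BED6), `truth.tsv` (BED-style coordinates plus direction and fold) and
#' one `geneset_*.txt` per gene set (`geneset_imprinted.tsv` keeps the
#' parent-of-origin column). Re-reading the bundle with
#' [read_fixture_bundle()] reproduces the in-memory objects.
#'
#' @param genome `toy_genome`.
#' @param signal Planted-signal `GRanges`.
#' @param reads_control,reads_exposed Read `GRanges`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(genome, signal, reads_control, reads_exposed,
                           out_dir) {
  stopifnot(inherits(genome, "toy_genome"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- c(
    chrom_sizes = file.path(out_dir, "chrom.sizes"),
    genes = file.path(out_dir, "genes.gff3"),
    cgis = file.path(out_dir, "cgis.bed"),
    repeats = file.path(out_dir, "repeats.bed"),
    cpg = file.path(out_dir, "cpg.bed"),
    reads_control = file.path(out_dir, "reads_control.bed"),
    reads_exposed = file.path(out_dir, "reads_exposed.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    imprinted = file.path(out_dir, "geneset_imprinted.tsv"))
  utils::write.table(data.frame(names(genome$chrom_sizes),
                                unname(genome$chrom_sizes)),
                     paths[["chrom_sizes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rtracklayer::export(.genes_to_gff(genome), paths[["genes"]], format = "gff3")
  rtracklayer::export(genome$cgis, paths[["cgis"]], format = "BED")
  reps <- genome$repeats
  reps$name <- reps$class
  reps$class <- NULL
  rtracklayer::export(reps, paths[["repeats"]], format = "BED")
  rtracklayer::export(genome$cpg, paths[["cpg"]], format = "BED")
  rtracklayer::export(reads_control, paths[["reads_control"]], format = "BED")
  rtracklayer::export(reads_exposed, paths[["reads_exposed"]], format = "BED")
  truth <- data.frame(
    chrom = if (length(signal)) as.character(GenomicRanges::seqnames(signal)) else character(0),
    start = if (length(signal)) GenomicRanges::start(signal) - 1L else integer(0),
    end = if (length(signal)) GenomicRanges::end(signal) else integer(0),
    direction = if (length(signal)) signal$direction else character(0),
    fold = if (length(signal)) signal$fold else numeric(0))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(genome$gene_sets)) {
    p <- file.path(out_dir, sprintf("geneset_%s.txt", nm))
    writeLines(genome$gene_sets[[nm]], p)
    paths[[paste0("geneset_", nm)]] <- p
  }
  utils::write.table(genome$imprinted, paths[["imprinted"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Gene models as a GFF3-ready GRanges: one `gene` record per gene plus one
# record per part (five_prime_UTR/exon/intron/three_prime_UTR, Parent set).
.genes_to_gff <- function(genome) {
  genes <- genome$genes
  part_type <- c(utr5 = "five_prime_UTR", exon = "exon", intron = "intron",
                 utr3 = "three_prime_UTR")
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    strand = genes$strand)
  gene_gr$type <- "gene"
  gene_gr$ID <- genes$gene_id
  gene_gr$Parent <- IRanges::CharacterList(vector("list", nrow(genes)))
  parts <- genome$parts
  part_gr <- GenomicRanges::granges(parts)
  part_gr$type <- unname(part_type[parts$part])
  part_gr$ID <- sprintf("%s.%s.%d", parts$gene_id, parts$part,
                        seq_along(parts))
  part_gr$Parent <- IRanges::CharacterList(as.list(parts$gene_id))
  out <- c(gene_gr, part_gr)
  GenomeInfoDb::seqlevels(out) <- names(genome$chrom_sizes)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Read a fixture bundle back into memory
#'
#' Inverse of [write_fixtures()]: reconstructs the toy-genome structure,
#' the truth table and the two read libraries from the on-disk bundle.
#'
#' @param dir Bundle directory.
#' @return List with the [write_fixtures()] components: chrom_sizes,
#'   window_width (NA until a grid is chosen), genes, parts, cgis,
#'   repeats, cpg, gene_sets, imprinted, truth (`GRanges` with direction
#'   and fold), reads_control, reads_exposed.
#' @export
read_fixture_bundle <- function(dir) {
  need <- file.path(dir, c("chrom.sizes", "genes.gff3", "reads_control.bed",
                           "reads_exposed.bed"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing fixture file(s): ", paste(missing, collapse = ", "))
  }
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  part_lab <- c(five_prime_UTR = "utr5", exon = "exon", intron = "intron",
                three_prime_UTR = "utr3")
  is_gene <- gff$type == "gene"
  gg <- gff[is_gene]
  genes <- data.frame(gene_id = gg$ID,
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      strand = as.character(GenomicRanges::strand(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  pp <- gff[as.character(gff$type) %in% names(part_lab)]
  parts <- GenomicRanges::granges(pp)
  parts$gene_id <- vapply(pp$Parent, `[`, character(1), 1L)
  parts$part <- unname(part_lab[as.character(pp$type)])
  cgis <- rtracklayer::import(file.path(dir, "cgis.bed"), format = "BED")
  reps <- rtracklayer::import(file.path(dir, "repeats.bed"), format = "BED")
  reps$class <- reps$name
  reps$name <- NULL
  cpg <- rtracklayer::import(file.path(dir, "cpg.bed"), format = "BED")
  set_files <- list.files(dir, pattern = "^geneset_.*\\.txt$",
                          full.names = TRUE)
  gene_sets <- lapply(set_files, read_gene_list)
  names(gene_sets) <- sub("^geneset_(.*)\\.txt$", "\\1", basename(set_files))
  imprinted <- NULL
  imp_path <- file.path(dir, "geneset_imprinted.tsv")
  if (file.exists(imp_path)) {
    imprinted <- utils::read.table(imp_path, sep = "\t", header = TRUE,
                                   colClasses = "character")
  }
  truth <- NULL
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    tt <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer", "integer",
                                           "character", "numeric"))
    truth <- GenomicRanges::GRanges(tt$chrom,
                                    IRanges::IRanges(tt$start + 1L, tt$end))
    truth$direction <- tt$direction
    truth$fold <- tt$fold
  }
  for (nm in c("cgis", "reps", "cpg")) {
    obj <- get(nm)
    GenomeInfoDb::seqlevels(obj) <- union(GenomeInfoDb::seqlevels(obj),
                                          names(cs))
    assign(nm, obj)
  }
  list(chrom_sizes = cs,
       genes = genes, parts = parts, cgis = cgis, repeats = reps, cpg = cpg,
       gene_sets = gene_sets[setdiff(names(gene_sets), "imprinted")],
       imprinted = imprinted, truth = truth,
       reads_control = rtracklayer::import(file.path(dir, "reads_control.bed"),
                                           format = "BED"),
       reads_exposed = rtracklayer::import(file.path(dir, "reads_exposed.bed"),
                                           format = "BED"))
}
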