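## Builds the packaged curated reference dataset under inst/extdata/.
## The tree topology for uncited nodes, the figure-level matrix cells, the
## gene neighbourhoods and the reference TrmFO sequence are curated/synthetic
## stand-ins; every text-anchored statement holds cell-by-cell (provenance
## column "text"). Re-run from the package root: Rscript data-raw/make_fixture.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## ---- species tree ---------------------------------------------------------

nwk <- paste0(
  "((Acholeplasma_laidlawii:0.22,(Candidatus_Phytoplasma_asteris:0.12,",
  "(Candidatus_Phytoplasma_australiense:0.08,Candidatus_Phytoplasma_mali:0.09)",
  "n40:0.05)2:0.10)3:0.08,",
  "(((Spiroplasma_citri:0.09,(Spiroplasma_melliferum:0.07,",
  "(Spiroplasma_chrysopicola:0.06,Spiroplasma_apis:0.08)n43:0.04)n42:0.04)",
  "n41:0.06,(Mesoplasma_florum:0.14,(Mycoplasma_auris:0.09,",
  "((Mycoplasma_yeatsii:0.05,Mycoplasma_putrefaciens:0.06)n47:0.04,",
  "((Mycoplasma_mycoides_subsp_mycoides:0.03,",
  "Mycoplasma_mycoides_subsp_capri:0.03)n48:0.02,",
  "(Mycoplasma_capricolum_subsp_capricolum:0.02,",
  "Mycoplasma_capricolum_subsp_capripneumoniae:0.02)n49:0.02)33:0.03)",
  "n46:0.03)34:0.05)n44:0.05)36:0.05,",
  "((((Mycoplasma_agalactiae:0.04,Mycoplasma_bovis:0.04)n51:0.08,",
  "(Mycoplasma_bovigenitalium_cl-51080:0.10,Mycoplasma_fermentans:0.12)",
  "n52:0.03)n50:0.04,",
  "(((Mycoplasma_hominis:0.10,Mycoplasma_arthritidis:0.11)n54:0.04,",
  "(Mycoplasma_pulmonis:0.13,Mycoplasma_mobile:0.12)n55:0.05)n53:0.03,",
  "(Mycoplasma_crocodyli:0.12,((Mycoplasma_synoviae:0.09,",
  "Mycoplasma_conjunctivae:0.10)n58:0.03,(Mycoplasma_hyorhinis:0.11,",
  "(Mycoplasma_hyopneumoniae:0.05,(Mycoplasma_flocculare:0.04,",
  "Mycoplasma_ovipneumoniae:0.05)n60:0.02)19:0.04)n59:0.03)n57:0.03)",
  "n56:0.03)n61:0.03)27:0.06,",
  "(((Mycoplasma_pneumoniae:0.08,Mycoplasma_genitalium:0.09)n63:0.05,",
  "(Mycoplasma_gallisepticum:0.10,Mycoplasma_imitans:0.09)n64:0.04)n62:0.05,",
  "((Mycoplasma_penetrans:0.11,Mycoplasma_iowae:0.10)n66:0.04,",
  "(Ureaplasma_parvum:0.05,Ureaplasma_urealyticum:0.05)n67:0.08)n65:0.06)",
  "12:0.08)28:0.05)37:0.06)38;"
)
writeLines(nwk, "inst/extdata/mollicutes_tree_curated.nwk")

tree <- ape::read.tree(text = nwk)
stopifnot(length(tree$tip.label) == 39L)
species <- tree$tip.label

## ---- species groups -------------------------------------------------------

grp <- function(sp) {
  if (grepl("Acholeplasma|Phytoplasma", sp)) return("AAP")
  if (grepl("Spiroplasma|Mesoplasma|auris|yeatsii|putrefaciens|mycoides|capricolum",
            sp)) return("S")
  if (grepl("pneumoniae$|_genitalium|gallisepticum|imitans|penetrans|iowae|Ureaplasma",
            sp) && !grepl("hyopneumoniae|ovipneumoniae|bovigenitalium", sp)) return("P")
  "H"
}
groups <- data.frame(species = species,
                     group = vapply(species, grp, ""),
                     mycoides_cluster = grepl("mycoides|capricolum", species),
                     stringsAsFactors = FALSE)
stopifnot(sum(groups$group == "AAP") == 4L, sum(groups$group == "S") == 12L,
          sum(groups$group == "H") == 15L, sum(groups$group == "P") == 8L,
          sum(groups$mycoides_cluster) == 4L)
write.table(groups, "inst/extdata/species_groups_curated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- phyletic matrix ------------------------------------------------------

families <- c("thyA", "tdk", "trmA", "rlmC", "rlmD", "rlmCD", "yfjO",
              "trmFO", "rlmFO", "trmFO_like", "rlmH")
abbr <- vapply(species, function(sp) {
  parts <- strsplit(sp, "_")[[1]]
  paste0(toupper(substr(parts[1], 1, 1)),
         toupper(substr(parts[length(parts)], 1, 4)))
}, "")
abbr <- setNames(make.unique(abbr, sep = ""), species)

m <- expand.grid(species = species, family = families,
                 stringsAsFactors = FALSE)
m$copy_count <- 0L
m$status <- "absent"
m$member_ids <- ""
m$provenance <- "curated"

set_cell <- function(sp, fam, copies, status, prov, ids = NULL) {
  i <- which(m$species == sp & m$family == fam)
  stopifnot(length(i) == 1L)
  m$copy_count[i] <<- as.integer(copies)
  m$status[i] <<- status
  m$provenance[i] <<- prov
  if (is.null(ids) && copies > 0) {
    ids <- if (copies == 1L) paste0(abbr[[sp]], "_", fam)
           else paste0(abbr[[sp]], "_", fam, "_", seq_len(copies))
  }
  m$member_ids[i] <<- paste(ids, collapse = ";")
}

## trmA / rlmC / rlmCD: no homolog in any mollicute (text)
m$provenance[m$family %in% c("trmA", "rlmC", "rlmCD")] <- "text"

## tdk: all but M. bovigenitalium cl-51080 (text)
for (sp in species) {
  if (sp == "Mycoplasma_bovigenitalium_cl-51080") {
    set_cell(sp, "tdk", 0, "absent", "text")
  } else {
    set_cell(sp, "tdk", 1, "functional", "text")
  }
}

## thyA: 16 carriers scattered over subgroups (count is text-anchored; the
## per-species assignment is curated)
thya <- c("Acholeplasma_laidlawii", "Spiroplasma_citri",
          "Spiroplasma_melliferum", "Spiroplasma_chrysopicola",
          "Spiroplasma_apis", "Mesoplasma_florum", "Mycoplasma_auris",
          "Mycoplasma_yeatsii", "Mycoplasma_putrefaciens",
          "Mycoplasma_hyorhinis", "Mycoplasma_hyopneumoniae",
          "Mycoplasma_flocculare", "Mycoplasma_ovipneumoniae",
          "Mycoplasma_pneumoniae", "Mycoplasma_genitalium",
          "Mycoplasma_gallisepticum")
stopifnot(length(thya) == 16L, all(thya %in% species))
for (sp in thya) set_cell(sp, "thyA", 1, "functional", "curated")

## rlmD: 4 paralogs in A. laidlawii (text); kept in the Hominis group except
## M. pulmonis and the node-19 subgroup; pseudogene in M. hyorhinis (text);
## absent from Spiroplasma (node 36) and Pneumoniae (node 12) groups (text)
set_cell("Acholeplasma_laidlawii", "rlmD", 4, "functional", "text")
rlmd_f <- c("Mycoplasma_agalactiae", "Mycoplasma_bovis",
            "Mycoplasma_bovigenitalium_cl-51080", "Mycoplasma_fermentans",
            "Mycoplasma_hominis", "Mycoplasma_arthritidis",
            "Mycoplasma_mobile", "Mycoplasma_crocodyli",
            "Mycoplasma_synoviae", "Mycoplasma_conjunctivae")
for (sp in rlmd_f) {
  prov <- if (sp %in% c("Mycoplasma_agalactiae", "Mycoplasma_bovis")) "text"
          else "curated"
  set_cell(sp, "rlmD", 1, "functional", prov)
}
set_cell("Mycoplasma_hyorhinis", "rlmD", 1, "pseudogene", "text")
for (sp in c("Mycoplasma_pulmonis", "Mycoplasma_hyopneumoniae",
             "Mycoplasma_ovipneumoniae")) {
  set_cell(sp, "rlmD", 0, "absent", "text")
}
m$provenance[m$species %in% species[groups$group %in% c("S", "P")] &
               m$family == "rlmD"] <- "text"

## yfjO: Acholeplasma-only expansion, >= 3 paralogs (text); lost elsewhere
set_cell("Acholeplasma_laidlawii", "yfjO", 3, "functional", "text")
m$provenance[grepl("Phytoplasma", m$species) & m$family == "yfjO"] <- "text"

## trmFO subgroup: A. laidlawii (2 copies, curated count) plus 4
## Spiroplasma-group species, S. citri as pseudogene (all text-anchored)
set_cell("Acholeplasma_laidlawii", "trmFO", 2, "functional", "text")
set_cell("Spiroplasma_citri", "trmFO", 1, "pseudogene", "text")
set_cell("Mesoplasma_florum", "trmFO", 1, "functional", "text")
set_cell("Mycoplasma_yeatsii", "trmFO", 1, "functional", "text")
set_cell("Mycoplasma_putrefaciens", "trmFO", 1, "functional", "text")
m$provenance[m$family == "trmFO" & m$status == "absent"] <- "text"

## rlmFO: Spiroplasma-group paralog born at node 36
set_cell("Spiroplasma_citri", "rlmFO", 1, "pseudogene", "text")
set_cell("Mesoplasma_florum", "rlmFO", 1, "functional", "text")
set_cell("Mycoplasma_auris", "rlmFO", 1, "functional", "text")
set_cell("Mycoplasma_yeatsii", "rlmFO", 1, "functional", "text")
set_cell("Mycoplasma_putrefaciens", "rlmFO", 1, "functional", "text")
set_cell("Mycoplasma_mycoides_subsp_mycoides", "rlmFO", 1, "functional",
         "curated")
set_cell("Mycoplasma_mycoides_subsp_capri", "rlmFO", 1, "functional",
         "curated")
set_cell("Mycoplasma_capricolum_subsp_capricolum", "rlmFO", 1, "functional",
         "text", ids = "MCAP_0476")
set_cell("Mycoplasma_capricolum_subsp_capripneumoniae", "rlmFO", 1,
         "pseudogene", "text")

## trmFO-like: ruminant clade under node 34 plus the HGT recipients
## M. agalactiae / M. bovis — nine sequences in all
set_cell("Mycoplasma_auris", "trmFO_like", 1, "functional", "curated")
set_cell("Mycoplasma_yeatsii", "trmFO_like", 1, "functional", "text")
set_cell("Mycoplasma_putrefaciens", "trmFO_like", 1, "functional", "text")
set_cell("Mycoplasma_mycoides_subsp_mycoides", "trmFO_like", 1, "functional",
         "curated")
set_cell("Mycoplasma_mycoides_subsp_capri", "trmFO_like", 1, "functional",
         "curated")
set_cell("Mycoplasma_capricolum_subsp_capricolum", "trmFO_like", 1,
         "functional", "text", ids = "MCAP_0613")
set_cell("Mycoplasma_capricolum_subsp_capripneumoniae", "trmFO_like", 1,
         "functional", "curated")
set_cell("Mycoplasma_agalactiae", "trmFO_like", 1, "functional", "text")
set_cell("Mycoplasma_bovis", "trmFO_like", 1, "functional", "text")

## rlmH: predicted in Me. florum / S. citri / M. agalactiae (text), present
## in M. capricolum subsp. capricolum and M. mycoides subsp. capri (text),
## retained across the Spiroplasma group, lost in several other groups
rlmh_f <- c("Acholeplasma_laidlawii", species[groups$group == "S"],
            "Mycoplasma_agalactiae", "Mycoplasma_bovis")
for (sp in rlmh_f) {
  prov <- if (sp %in% c("Mesoplasma_florum", "Spiroplasma_citri",
                        "Mycoplasma_agalactiae",
                        "Mycoplasma_capricolum_subsp_capricolum",
                        "Mycoplasma_mycoides_subsp_capri")) "text"
          else "curated"
  set_cell(sp, "rlmH", 1, "functional", prov)
}

## order rows species-major, family order as declared
m <- m[order(match(m$species, species), match(m$family, families)), ]
write.table(m, "inst/extdata/phyletic_matrix_curated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## consistency: paper counts
trm_rel <- c("trmFO", "rlmFO", "trmFO_like")
sub <- m[m$family %in% trm_rel & m$status != "absent", ]
tot <- tapply(sub$copy_count, sub$species, sum)
stopifnot(length(tot) == 12L, sum(tot > 1L) == 10L)
stopifnot(sum(m$family == "trmFO" & m$status != "absent") == 5L)

## ---- phenotypes (empirically assayed species) -----------------------------

ph <- function(sp, m5u54, m5u1939, cm1920, m3u1915, m5u747) {
  data.frame(species = sp,
             site = c("m5U54_tRNA", "m5U1939_23S", "Cm1920_23S",
                      "m3U1915_23S", "m5U747_23S"),
             state = c(m5u54, m5u1939, cm1920, m3u1915, m5u747),
             stringsAsFactors = FALSE)
}
P <- "present"; A <- "absent"; ND <- "not_determined"
phen <- rbind(
  ph("Acholeplasma_laidlawii",                 P, P, P, P, A),
  ph("Mesoplasma_florum",                      P, P, P, A, A),
  ph("Spiroplasma_citri",                      A, A, P, A, A),
  ph("Mycoplasma_agalactiae",                  A, P, A, A, A),
  ph("Mycoplasma_auris",                       A, P, A, P, A),
  ph("Mycoplasma_mobile",                      A, ND, ND, ND, ND),
  ph("Mycoplasma_capricolum_subsp_capricolum", A, P, P, P, A),
  ph("Mycoplasma_gallisepticum",               A, A, A, A, A)
)
write.table(phen, "inst/extdata/phenotypes_curated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- gene neighbourhoods (synthetic) --------------------------------------

nb_rows <- function(anchor, fams) {
  n <- length(fams)
  ## first family sits immediately downstream (+1), then alternate sides
  off <- as.integer(ceiling(seq_len(n) / 2) * rep_len(c(1L, -1L), n))
  data.frame(anchor = anchor, offset = off, ortholog_family = fams,
             strand = rep(c("+", "-"), length.out = n),
             stringsAsFactors = FALSE)
}
trmfo_core <- c("mnmG", "rsmG", "jag", "spoIIIJ", "rnpA")
rlmfo_core <- c("rpsB", "tsf", "pyrH", "frr", "uppS")
like_core  <- c("folT", "ecfA", "ecfT", "glpK", "ldh")

nb <- rbind(
  ## trmFO subgroup: Gram-positive-like gene order
  nb_rows("BSUB_trmFO", c(trmfo_core, "parB")),           ## reference genome
  nb_rows("ALAID_trmFO_1", c(trmfo_core, "dnaA")),
  nb_rows("ALAID_trmFO_2", c("mnmG", "rsmG", "jag", "dnaA", "ftsH", "secA")),
  nb_rows("SCITR_trmFO", c("mnmG", "rsmG", "jag", "parB")),
  nb_rows("MFLOR_trmFO", c(trmfo_core, "parB")),
  nb_rows("MYEAT_trmFO", c(trmfo_core, "ftsH")),
  nb_rows("MPUTR_trmFO", c(trmfo_core, "secA")),
  ## rlmFO: highly conserved even among remote Spiroplasma-group species
  nb_rows("MCAP_0476", c(rlmfo_core, "cdsA")),
  nb_rows("SCITR_rlmFO", c(rlmfo_core, "cdsA")),
  nb_rows("MFLOR_rlmFO", c(rlmfo_core, "dnaJ")),
  nb_rows("MAURI_rlmFO", c(rlmfo_core, "cdsA")),
  nb_rows("MYEAT_rlmFO", c(rlmfo_core, "cdsA")),
  nb_rows("MPUTR_rlmFO", c(rlmfo_core, "dnaJ")),
  nb_rows("MMYCO_rlmFO", c(rlmfo_core, "cdsA")),
  nb_rows("MCAPR_rlmFO", c(rlmfo_core, "cdsA")),
  ## trmFO-like: only moderate conservation; folT immediately downstream
  nb_rows("MCAP_0613", c("folT", "ecfA", "glpK", "oppA", "gatA", "pdhA")),
  nb_rows("MAURI_trmFO_like", c("folT", "ecfT", "ldh", "oppB", "gatB", "nox")),
  nb_rows("MYEAT_trmFO_like", c("folT", "ecfA", "ecfT", "oppC", "pdhB", "ackA")),
  nb_rows("MPUTR_trmFO_like", c("folT", "glpK", "ldh", "oppD", "pta", "adk")),
  nb_rows("MAGAL_trmFO_like", c("folT", "vpmA", "tnpA", "oppF", "gapA", "pgk")),
  nb_rows("MBOVI_trmFO_like", c("folT", "vspA", "tnpA", "oppF", "gapA", "eno"))
)
write.table(nb, "inst/extdata/neighborhoods_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

profiles <- list(
  trmFO = list(window = 5L,
               sets = list(c(trmfo_core, "parB"), c(trmfo_core, "dnaA"))),
  rlmFO = list(window = 5L,
               sets = list(c(rlmfo_core, "cdsA"), c(rlmfo_core, "dnaJ"))),
  trmFO_like = list(window = 5L,
                    sets = list(c("folT", "ecfA", "ecfT", "glpK", "ldh")))
)
jsonlite::write_json(profiles, "inst/extdata/context_profiles_synthetic.json",
                     auto_unbox = TRUE, pretty = TRUE)

## ---- synthetic reference TrmFO (coordinates follow T. thermophilus) -------

set.seed(3951L)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ref <- sample(aa, 445, replace = TRUE)
ref[10:18] <- strsplit("GAGTAGLEA", "")[[1]]   ## FAD pyrophosphate motif
ref[51] <- "C"; ref[223] <- "C"                ## catalytic cysteines
ref[308] <- "H"; ref[309] <- "R"; ref[310] <- "N"  ## folate triad
ref[343] <- "Y"                                ## flavin stack
## avoid accidental extra motif matches
refseq <- paste(ref, collapse = "")
stopifnot(identical(gregexpr("GAG[A-Z][AS]G[A-Z]E[AV]", refseq)[[1]][1], 10L))
writeLines(c(">TrmFO_Tth_synthetic coordinates follow T. thermophilus TrmFO (PDB 3G5S); sequence is a synthetic stand-in",
             paste(substring(refseq, seq(1, 445, 60),
                             pmin(seq(1, 445, 60) + 59, 445)), collapse = "\n")),
           "inst/extdata/reference_trmfo_synthetic.fasta")

annotation <- list(
  reference_id = "TrmFO_Tth_synthetic",
  catalytic_positions = c(51L, 223L),
  folate_triad_positions = c(308L, 309L, 310L),
  flavin_stack_position = 343L,
  fad_motif_pattern = "GAGx[A/S]GxE[A/V]",
  note = paste("Synthetic stand-in for T. thermophilus TrmFO (PDB 3G5S);",
               "the annotated coordinates are the published ones, the",
               "sequence background is random.")
)
jsonlite::write_json(annotation, "inst/extdata/reference_annotation.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("fixture written\n")
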