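#!/usr/bin/env Rscript
# Build the synthetic study system: a two-lineage phylogeny (a heteroatom-
# oxidizing "SN" clade and a Baeyer-Villiger "BV" clade) with named
# ancestors at the pre- and post-duplication nodes, an alignment evolved
# under JTT + discrete gamma (alpha 1.114, 4 categories), and a
# clade-restricted block deletion so the Fitch gap machinery has work to
# do. Inputs for the downstream scripts land in results/data/.

suppressMessages(library(paleofmo))
suppressMessages(library(ape))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## two ingroup clades of 8 leaves plus a 4-leaf outgroup rooting the tree
## (the bony-fish analog); the branch between the pre-duplication ancestor
## "anc_all" and the SN ancestor "anc_SN" is the focal branch of the
## substitution funnel
sn <- "(sn1:0.08,(sn2:0.06,sn3:0.07):0.05,((sn4:0.05,sn5:0.09):0.04,(sn6:0.06,sn7:0.08,sn8:0.05):0.06):0.05)anc_SN:0.12"
bv <- "(bv1:0.07,(bv2:0.08,bv3:0.05):0.06,((bv4:0.06,bv5:0.07):0.05,(bv6:0.09,bv7:0.05,bv8:0.06):0.04):0.06)anc_BV:0.12"
og <- "(og1:0.10,og2:0.15,(og3:0.10,og4:0.10):0.08)outgroup:0.25"
tree <- read.tree(text = sprintf("((%s,%s)anc_all:0.18,%s)root;",
                                 sn, bv, og))

model <- build_model("JTT", alpha = 1.114, K = 4)
n_sites <- 300

## the BV lineage loses a 12-column block on its stem (clade-specific gap)
sim <- simulate_alignment(tree, model, n_sites,
                          indel_spec = list(list(node = "anc_BV",
                                                 columns = 101:112)),
                          seed = 11)

write_fasta(sim$alignment, "results/data/msa.fasta")
write_newick(tree, "results/data/tree.nwk")
writeLines(paste0("sn", 1:8), "results/data/sn_clade.txt")
writeLines(paste0("bv", 1:8), "results/data/bv_clade.txt")

## structural annotation of the SN-ancestor residues: a small active site,
## tunnel and cofactor shells, the rest unannotated surface/core
set.seed(12)
n_res <- sum(fitch_gap_mask(sim$alignment, tree, "anc_SN")$present)
categories <- rep("other", n_res)
categories[sample(n_res, 24)] <- "active_site"
categories[sample(which(categories == "other"), 20)] <- "tunnel"
categories[sample(which(categories == "other"), 16)] <- "FAD_proximal"
categories[sample(which(categories == "other"), 16)] <- "NADPH_shell1"
categories[sample(which(categories == "other"), 16)] <- "NADPH_shell2"
ann <- data.frame(position = seq_len(n_res),
                  category = categories,
                  location = sample(c("surface", "core"), n_res,
                                    replace = TRUE, prob = c(0.55, 0.45)),
                  domain = sample(c("FAD_binding", "NADPH_binding",
                                    "insertion_80res"), n_res,
                                  replace = TRUE, prob = c(0.5, 0.3, 0.2)))
write.table(ann, "results/data/annotations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## ground truth sidecar for the recovery report in 02
saveRDS_path <- "results/data/truth_root.txt"
writeLines(paste(sim$truth$sequences["anc_all", ], collapse = ""),
           saveRDS_path)
writeLines(paste(sim$truth$sequences["anc_SN", ], collapse = ""),
           "results/data/truth_anc_SN.txt")

cat(sprintf("simulated %d leaves x %d sites; %d residues annotated\n",
            length(sim$alignment$ids), n_sites, n_res))
cat("inputs written under results/data/\n")
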