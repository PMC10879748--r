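# Reanalysis of reticulate evolution in the genus Canis (optional example).
#
# This script is NOT run by the package tests: it needs the published gene
# trees of Zhang et al.'s weighted-ASTRAL data collection, available from
#   https://github.com/chaoszhang/Weighted-ASTRAL_data
# (the canid dataset of ~449k estimated gene trees, originally from the
# genomic study of gray wolves and relatives).  Download the gene-tree file
# and a two-column individual-to-species map, then point the paths below at
# them.
#
# The analysis subsamples one individual each of African hunting dog,
# coyote, dhole, dog, golden jackal, and gray wolf — six taxa, so the
# 1080-candidate enumeration applies directly — and asks which placement of
# a four-node hybridization cycle best fits the quartet concordance
# factors.  The expected result is gene flow from the ancestor of dog and
# gray wolf into the ancestor of the golden jackal: the top-ranked network
# puts golden jackal below the hybrid node with dog/gray wolf on one parent
# side.

library(quartetinv)

gene_tree_file <- "canis_gene_trees.nwk"   # one Newick tree per line
taxon_map_file <- "canis_taxon_map.csv"    # columns: individual, taxon

stopifnot(file.exists(gene_tree_file), file.exists(taxon_map_file))

trees <- readLines(gene_tree_file)
mapping <- read.csv(taxon_map_file, stringsAsFactors = FALSE,
                    colClasses = "character")
names(mapping) <- c("individual", "taxon")

taxa <- c("african_hunting_dog", "coyote", "dhole",
          "dog", "golden_jackal", "gray_wolf")

cf <- cfs_from_gene_trees(trees, taxa = taxa, mapping = mapping)
write_cf_table(cf, "canis_cf_table.csv")

ranking <- rank_partitions(cf, m = 5)
print(top_networks(ranking))
writeLines(as_enewick(parse_partition(ranking$partition[1])),
           "canis_best.enewick")
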