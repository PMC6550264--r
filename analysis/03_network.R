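#!/usr/bin/env Rscript
# Build the weighted patient-sharing network from the extracted transitions
# and summarise its density and weight distribution.
suppressMessages({ library(carefrag); library(data.table) })

tr <- fread("results/transitions.csv",
            colClasses = list(character = c("patient_id", "from_provider", "to_provider")))
if (is.character(tr$fragmented)) tr[, fragmented := fragmented == "true"]
truth <- jsonlite::read_json("results/synthetic/ground_truth.json")
net <- build_network(tr, node_universe = names(truth$provider_community))
print(net)

s <- network_summary(net, thresholds = c(10, 50))
cat(sprintf("density: %d/%d possible edges (%.1f%%)\n",
            s$n_edges, s$n_possible, s$density_pct))
print(s$threshold_counts)

write_edge_list(net, "results/edge_list.tsv")
write_graphml(net, "results/network.graphml")
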