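"element","compartment","amount","group","replicate"
"B","nucleus",60.990154175916,"treated",1
"B","nucleus",62.6282178498251,"treated",2
"B","nucleus",60.2275824886624,"treated",3
"B","nucleus",62.4049675238523,"treated",4
"B","nucleus",57.5800311495967,"treated",5
"B","nucleus",60.4372898614956,"treated",6
"Fe","nucleus",15.7185851707344,"treated",1
"Fe","nucleus",17.9906860046078,"treated",2
"Fe","nucleus",16.5219921129587,"treated",3
"Fe","nucleus",15.058025720242,"treated",4
"Fe","nucleus",15.9048172518101,"treated",5
"Fe","nucleus",18.7827592665135,"treated",6
"B","cytoplasm",96.5106567865599,"treated",1
"B","cytoplasm",69.728063365427,"treated",2
"B","cytoplasm",66.1217168624864,"treated",3
"B","cytoplasm",89.5557215643885,"treated",4
"B","cytoplasm",86.1018226523644,"treated",5
"B","cytoplasm",75.2462183943231,"treated",6
"Fe","cytoplasm",27.0102862756165,"treated",1
"Fe","cytoplasm",26.403764999088,"treated",2
"Fe","cytoplasm",28.6770602435406,"treated",3
"Fe","cytoplasm",27.7030589571133,"treated",4
"Fe","cytoplasm",25.547812951021,"treated",5
"Fe","cytoplasm",24.8313609314724,"treated",6
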