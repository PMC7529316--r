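{"pathways":[{"id":"PWY0001","name":"synthetic pathway 1","reactions":["1.1.1.1","7.7.7.7","6.13.13.13","5.6.19.19"],"key_reactions":["6.13.13.13"],"taxonomic_range":[],"hierarchy":[]},{"id":"PWY0002","name":"synthetic pathway 2","reactions":["2.2.2.2","1.8.8.8","7.1.14.14","6.7.20.20","3.3.3.3"],"key_reactions":["2.2.2.2"],"taxonomic_range":[],"hierarchy":[]},{"id":"PWY0003","name":"synthetic pathway 3","reactions":["3.3.3.3","2.9.9.9","1.2.15.15","7.8.21.21"],"key_reactions":["3.3.3.3"],"taxonomic_range":[],"hierarchy":[]},{"id":"PWY0004","name":"synthetic pathway 4","reactions":["4.4.4.4","3.10.10.10","2.3.16.16","1.9.22.22"],"key_reactions":["3.10.10.10"],"taxonomic_range":[],"hierarchy":[]},{"id":"PWY0005","name":"synthetic pathway 5","reactions":["5.5.5.5","4.11.11.11","3.4.17.17","2.10.23.23"],"key_reactions":["3.4.17.17"],"taxonomic_range":[],"hierarchy":[]},{"id":"PWY0006","name":"synthetic pathway 6","reactions":["6.6.6.6","5.12.12.12","4.5.18.18","3.11.24.24","3.10.10.10"],"key_reactions":["4.5.18.18"],"taxonomic_range":[],"hierarchy":[]}]}
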