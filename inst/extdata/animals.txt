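# Toy animal lexicon for intrusion detection and simulation.
# One canonical item per line; user-replaceable with any category lexicon.
dog
cat
horse
cow
pig
sheep
goat
chicken
duck
goose
turkey
rabbit
mouse
rat
squirrel
chipmunk
deer
elk
moose
bear
wolf
fox
coyote
raccoon
skunk
opossum
bat
lion
tiger
leopard
cheetah
jaguar
elephant
rhinoceros
hippopotamus
giraffe
zebra
camel
llama
alpaca
monkey
gorilla
chimpanzee
orangutan
lemur
kangaroo
koala
platypus
whale
dolphin
seal
walrus
otter
beaver
penguin
eagle
hawk
owl
crow
robin
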