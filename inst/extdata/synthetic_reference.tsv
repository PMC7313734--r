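alpaca	bat
alpaca	bear
alpaca	cat
alpaca	coyote
alpaca	llama
alpaca	wolf
alpaca	zebra
bat	bear
bat	chimpanzee
bat	horse
bear	beaver
bear	camel
bear	rabbit
beaver	camel
beaver	cat
beaver	hippopotamus
beaver	rhinoceros
beaver	whale
camel	cheetah
cat	cheetah
cat	lion
cheetah	chicken
cheetah	chimpanzee
chicken	chimpanzee
chicken	tiger
chimpanzee	chipmunk
chimpanzee	cow
chipmunk	cow
chipmunk	coyote
chipmunk	lion
cow	coyote
cow	crow
coyote	deer
crow	deer
crow	dog
deer	dog
deer	dolphin
deer	seal
dog	dolphin
dog	duck
dolphin	duck
dolphin	eagle
duck	eagle
duck	elephant
eagle	elephant
eagle	elk
elephant	elk
elephant	fox
elk	fox
elk	giraffe
fox	giraffe
fox	goat
fox	leopard
giraffe	goat
goat	goose
goat	gorilla
goose	gorilla
goose	hawk
goose	tiger
gorilla	hawk
gorilla	hippopotamus
hawk	hippopotamus
hawk	horse
hippopotamus	jaguar
hippopotamus	platypus
horse	jaguar
horse	kangaroo
jaguar	kangaroo
jaguar	koala
kangaroo	koala
kangaroo	lemur
koala	lemur
koala	leopard
lemur	lion
leopard	lion
leopard	llama
lion	monkey
llama	monkey
llama	moose
llama	orangutan
monkey	moose
monkey	pig
moose	mouse
moose	opossum
mouse	opossum
mouse	orangutan
mouse	zebra
opossum	orangutan
opossum	otter
orangutan	otter
orangutan	owl
otter	owl
otter	penguin
owl	penguin
penguin	pig
penguin	squirrel
pig	platypus
pig	rabbit
platypus	raccoon
platypus	sheep
rabbit	rat
raccoon	rat
raccoon	rhinoceros
rat	robin
rhinoceros	robin
rhinoceros	seal
robin	seal
robin	sheep
seal	sheep
sheep	skunk
sheep	squirrel
skunk	squirrel
squirrel	tiger
tiger	turkey
tiger	walrus
turkey	walrus
walrus	whale
walrus	wolf
whale	wolf
whale	zebra
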