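term,category
i,self_ref
im,self_ref
me,self_ref
my,self_ref
mine,self_ref
myself,self_ref
a,article
an,article
the,article
happy,posemo
love,posemo
great,posemo
joy,posemo
excited,posemo
smile,posemo
good,posemo
amazing,posemo
hope,posemo
fun,posemo
sad,negemo
cry,negemo
hate,negemo
tired,negemo
pain,negemo
alone,negemo
depressed,negemo
awful,negemo
anxious,negemo
worthless,negemo
empty,negemo
hurt,negemo
damn,swear
crap,swear
hell,swear
shit,swear
fuck,swear
wtf,swear
lol,netspeak
omg,netspeak
lmao,netspeak
thx,netspeak
brb,netspeak
idk,netspeak
think,cogproc
believe,cogproc
realize,cogproc
know,cogproc
because,cogproc
reason,cogproc
work,work
office,work
meeting,work
project,work
boss,work
deadline,work
money,money
taxes,money
rent,money
budget,money
salary,money
bills,money
heart,body
ache,body
head,body
blood,body
skin,body
bones,body
crush,sexual
kiss,sexual
cuddle,sexual
family,family
mom,family
dad,family
sister,family
brother,family
grandma,family
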